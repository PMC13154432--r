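test_that("collinearity index on constructed matrices matches theory", {
  # orthonormal columns
  Q <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  colnames(Q) <- c("p1", "p2", "p3", "p4")
  expect_equal(collinearity_index(Q), 1, tolerance = 1e-10)
  # identical columns are singular
  D <- cbind(a = rnorm(10))
  D <- cbind(D, b = D[, 1])
  expect_identical(collinearity_index(D), Inf)
  # a zero column is degenerate
  Z <- cbind(a = rnorm(10), b = 0)
  expect_identical(collinearity_index(Z), Inf)
  # size-1 subsets give 1 by convention
  expect_equal(collinearity_index(D, "a"), 1)
})

test_that("gamma is invariant to column scaling and row permutation", {
  set.seed(4)
  M <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  g0 <- collinearity_index(M)
  expect_equal(collinearity_index(sweep(M, 2, c(10, 0.01, 3), "*")), g0)
  expect_equal(collinearity_index(M[sample(20), ]), g0)
})

test_that("gamma of a subset never exceeds gamma of its superset", {
  S <- relative_sensitivities(reference_params(), roi_geometry(),
                              noiseless_set()$noiseless,
                              solver = quick_solver())
  g_full <- collinearity_index(S)
  for (ss in combn(colnames(S), 2, simplify = FALSE))
    expect_lte(collinearity_index(S, ss), g_full + 1e-9)
  for (ss in combn(colnames(S), 3, simplify = FALSE))
    expect_lte(collinearity_index(S, ss), g_full + 1e-9)
})

test_that("production gamma agrees with an SVD oracle to 1e-8", {
  S <- relative_sensitivities(reference_params(), roi_geometry(),
                              noiseless_set()$noiseless,
                              solver = quick_solver())
  Sn <- sweep(S, 2, sqrt(colSums(S^2)), "/")
  oracle <- 1 / min(svd(Sn)$d)
  expect_equal(collinearity_index(S), oracle, tolerance = 1e-8)
})

test_that("structurally inert parameters give a zero sensitivity column", {
  p0 <- model_parameters(128, 0, 0.08, 0.38)
  pulse <- generate_input_pulse(synthetic_config(params = p0, noise_cv = 0))
  # with a12 = 0 nothing reaches compartment 2, so b has no pathway
  S <- relative_sensitivities(p0, roi_geometry(), pulse,
                              free = c("s_ph", "b"),
                              solver = quick_solver())
  expect_true(all(abs(S[, "b"]) < 1e-10))
  expect_true(any(abs(S[, "s_ph"]) > 1e-6))
})

test_that("parameters on a bound fall back to a one-sided difference with a warning", {
  p0 <- model_parameters(128, 0, 0.08, 0.38)
  pulse <- generate_input_pulse(synthetic_config(params = p0, noise_cv = 0))
  expect_warning(
    relative_sensitivities(p0, roi_geometry(), pulse,
                           free = c("a12", "c"), solver = quick_solver()),
    "lower bound")
})

test_that("sensitivities are robust to the finite-difference step", {
  set <- noiseless_set()
  S1 <- relative_sensitivities(reference_params(), roi_geometry(),
                               set$noiseless, rel_step = 1e-4,
                               solver = quick_solver())
  S2 <- relative_sensitivities(reference_params(), roi_geometry(),
                               set$noiseless, rel_step = 2e-4,
                               solver = quick_solver())
  rel <- abs(S2 - S1) / pmax(abs(S1), 1e-6)
  expect_lt(stats::quantile(rel, 0.99), 0.01)
})

test_that("literature-magnitude parameters are identifiable below the threshold", {
  set <- noiseless_set()
  S <- relative_sensitivities(reference_params(), roi_geometry(),
                              set$noiseless, solver = quick_solver())
  expect_true(all(sqrt(colSums(S^2)) > 1e-4))  # every column informative
  rep <- assess_identifiability(S = S, threshold = 15)
  expect_s3_class(rep, "identifiability_report")
  expect_identical(attr(rep, "threshold"), 15)
  full <- rep[rep$size == 4, ]
  expect_lt(full$gamma, 15)
  expect_true(all(rep$identifiable))
})

test_that("the data-visible surface is much worse conditioned than the state surface", {
  set <- noiseless_set()
  S_states <- relative_sensitivities(reference_params(), roi_geometry(),
                                     set$noiseless, solver = quick_solver())
  S_obs <- relative_sensitivities(reference_params(), roi_geometry(),
                                  set$noiseless, surface = "observed",
                                  normalization = "rms",
                                  solver = quick_solver())
  expect_gt(collinearity_index(S_obs), 5 * collinearity_index(S_states))
})
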