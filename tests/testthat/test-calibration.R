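test_that("objective is zero at the generating parameters and reports offsets exactly", {
  set <- noiseless_set()
  g <- roi_geometry()
  expect_lt(rmse_objective(reference_params(), set$noiseless, g,
                           solver = quick_solver()), 1e-10)

  shifted <- set$noiseless
  delta <- 0.037
  for (nm in c("roi1", "roi2", "roi3"))
    shifted[[nm]] <- shifted[[nm]] + delta
  expect_equal(rmse_objective(reference_params(), shifted, g,
                              solver = quick_solver()),
               delta, tolerance = 1e-6)
})

test_that("objective at injected noise equals the residual norm of the noise", {
  cfg <- synthetic_config(noise_cv = 0.05, seed = 31)
  set <- generate_roi_set(cfg, solver = quick_solver())
  g <- roi_geometry()
  # noise was injected into all 4 columns, but the objective sees only
  # rois 1-3 (and is driven by the noisy input column)
  noisy_forced <- set$noisy
  for (nm in c("roi1", "roi2", "roi3"))
    noisy_forced[[nm]] <- set$noiseless[[nm]]
  base <- simulate_tacs(reference_params(), g, noisy_forced,
                        solver = quick_solver())
  resid <- as.matrix(set$noisy[c("roi1", "roi2", "roi3")]) -
    as.matrix(base$frames[c("roi1", "roi2", "roi3")])
  expect_equal(rmse_objective(reference_params(), set$noisy, g,
                              solver = quick_solver()),
               sqrt(mean(resid^2)), tolerance = 1e-9)
})

test_that("shuffled complex evolution minimizes a known smooth function", {
  set.seed(1)
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  res <- sce_ua(rosen, lower = c(-5, -5), upper = c(5, 5),
                n_complexes = 5, max_evaluations = 3000, accuracy = 0)
  expect_lt(res$value, 1e-6)
  expect_equal(unname(res$par), c(1, 1), tolerance = 1e-2)
  expect_lte(res$n_evaluations, 3002)
})

test_that("noiseless calibration recovers the generating parameters", {
  fit <- reference_fit()
  tr <- reference_params()
  p <- fit$params
  rel <- abs(c(p$s_ph / tr$s_ph, p$a12 / tr$a12, p$b / tr$b, p$c / tr$c) - 1)
  expect_lt(max(rel), 0.02)
  expect_identical(p$h, 0.68759)  # fixed constant when h is not free
  expect_lt(fit$rmse, 1e-4)
})

test_that("degenerate truth a12 = 0 is fitted at the lower bound", {
  p0 <- model_parameters(128, 0, 0.08, 0.38)
  set <- generate_roi_set(synthetic_config(params = p0, noise_cv = 0),
                          solver = quick_solver())
  fit <- calibrate(set$noiseless, roi_geometry(),
                   calibration_config(seed = 3, max_evaluations = 2000,
                                      solver = quick_solver()))
  expect_lt(fit$params$a12, 0.005)
})

test_that("identical seed and data give a bit-identical result", {
  set <- noiseless_set()
  cfg <- calibration_config(seed = 17, max_evaluations = 600,
                            solver = quick_solver())
  f1 <- calibrate(set$noiseless, roi_geometry(), cfg)
  f2 <- calibrate(set$noiseless, roi_geometry(), cfg)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$rmse, f2$rmse)
  expect_identical(f1$n_evaluations, f2$n_evaluations)
})

test_that("rescaling every TAC column leaves the fitted parameters unchanged", {
  set <- noiseless_set()
  cfg <- calibration_config(seed = 23, max_evaluations = 1500,
                            solver = quick_solver())
  f1 <- calibrate(set$noiseless, roi_geometry(), cfg)
  f10 <- calibrate(phloempet:::scale_tac(set$noiseless, 10),
                   roi_geometry(), cfg)
  for (nm in c("s_ph", "a12", "b", "c"))
    expect_equal(f1$params[[nm]], f10$params[[nm]], tolerance = 1e-10)
  # the objective scales with the data; agreement is limited only by the
  # solver's absolute-tolerance interaction with the rescaled state
  expect_equal(f10$rmse, 10 * f1$rmse, tolerance = 1e-6)
})

test_that("five-parameter calibration recovers the coupling constant", {
  tr <- model_parameters(128, 0.27, 0.08, 0.38, h = 0.6875)
  set <- generate_roi_set(synthetic_config(params = tr, noise_cv = 0),
                          solver = quick_solver())
  # 2n+1 rule gives 11 complexes for five parameters
  cfg <- calibration_config(n_complexes = 11, seed = 1,
                            solver = quick_solver())
  fit <- calibrate_five_param(set$noiseless, roi_geometry(), cfg)
  expect_lt(abs(fit$params$h / tr$h - 1), 0.05)
  expect_setequal(fit$free_parameters, c("s_ph", "a12", "b", "c", "h"))
})

test_that("config validation and the h averaging rule behave as documented", {
  expect_s3_class(calibration_config(n_complexes = 11), "calibration_config")
  expect_error(calibration_config(n_complexes = 1), "n_complexes")
  expect_error(calibration_config(bounds = list(s_ph = c(1, Inf), a12 = c(0, 1),
                                                b = c(0, 1), c = c(0, 1),
                                                h = c(0, 1))),
               "finite")
  expect_error(calibration_config(bounds = list(s_ph = c(1, 500),
                                                a12 = c(0, 2), b = c(0, 1),
                                                c = c(0, 1), h = c(0, 1))),
               "\\[0, 1\\]")
  expect_equal(average_h(c(0.6, 0.7, 0.76)), 0.6867)
})

test_that("objective at the truth beats nearby perturbed parameter vectors", {
  set <- noiseless_set()
  g <- roi_geometry()
  sol <- quick_solver()
  f0 <- rmse_objective(reference_params(), set$noiseless, g, sol)
  tr <- reference_params()
  for (fac in c(0.9, 1.1)) {
    for (nm in c("s_ph", "a12", "b", "c")) {
      v <- list(s_ph = tr$s_ph, a12 = tr$a12, b = tr$b, c = tr$c)
      v[[nm]] <- v[[nm]] * fac
      f <- rmse_objective(model_parameters(v$s_ph, v$a12, v$b, v$c),
                          set$noiseless, g, sol)
      expect_gt(f, f0)
    }
  }
})
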