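test_that("advective rate constant converts um/s and mm to 1/s", {
  expect_equal(advective_rate_constant(model_parameters(128, 0.27, 0.08, 0.38),
                                       roi_geometry(roi_length_mm = 4)),
               0.032)
  expect_equal(advective_rate_constant(model_parameters(70, 0.07, 0.25, 0.30),
                                       roi_geometry(roi_length_mm = 10)),
               0.007)
  expect_error(model_parameters(0, 0.1, 0.1, 0.1), "s_ph")
  expect_error(roi_geometry(roi_length_mm = -1), "roi_length_mm")
})

test_that("parameter constructor enforces ranges and derives a21", {
  p <- model_parameters(100, 0.2, 0.1, 0.3, h = 0.5)
  expect_identical(p$a21, 0.5 * 0.2)
  expect_error(model_parameters(100, 1.2, 0.1, 0.3), "a12")
  expect_error(model_parameters(100, 0.2, -0.1, 0.3), "'b'")
  expect_error(model_parameters(100, 0.2, 0.1, 0.3, h = 0), "'h'")
  expect_error(model_parameters(100, 0.2, 0.1, 0.3, h = 1.4), "'h'")
})

test_that("input ROI closure subtracts simulated compartments and floors at zero", {
  expect_equal(input_c1(1.0, 0.3, 0.2), 0.5)
  expect_equal(input_c1(0, 0, 0), 0)
  expect_equal(input_c1(0.1, 0.15, 0), 0)
})

test_that("derivatives vanish at the origin and respect structural zeros", {
  p <- reference_params()
  g <- roi_geometry()
  zero_in <- function(t) 0
  d <- phloem_derivatives(0, numeric(14), p, g, zero_in)
  expect_true(all(d == 0))
  expect_error(phloem_derivatives(0, numeric(5), p, g, zero_in), "14")

  # with a12 = 0 nothing ever enters C2/C3
  p0 <- model_parameters(128, 0, 0.08, 0.38)
  cfg <- synthetic_config(params = p0, noise_cv = 0)
  sim <- simulate_tacs(p0, g, generate_input_pulse(cfg))
  c23 <- unlist(sim$dense[c("C2_input", "C3_input", "C2_roi1", "C3_roi1",
                            "C2_roi2", "C3_roi2", "C2_roi3", "C3_roi3")])
  expect_true(all(abs(c23) < 1e-12))
})

test_that("advection cascade with a12 = 0 matches the Erlang step response", {
  A <- 2.5
  p <- model_parameters(128, 0, 0, 0)
  g <- roi_geometry()
  k_min <- 60 * advective_rate_constant(p, g)  # 1.92 per min
  const_input <- structure(
    data.frame(time_min = seq(2.5, 117.5, by = 5), input = A),
    frame_width_min = 5)
  sim <- simulate_tacs(p, g, const_input)
  t <- sim$dense$time_min
  for (i in 1:3) {
    expected <- A * pgamma(t, shape = i, rate = k_min)
    got <- sim$dense[[paste0("C1_roi", i)]]
    expect_lt(max(abs(got - expected)) / A, 1e-4)
  }
})

test_that("zero input yields identically zero output and zero balance residual", {
  p <- reference_params()
  g <- roi_geometry()
  zero_tac <- structure(
    data.frame(time_min = seq(2.5, 117.5, by = 5), input = 0),
    frame_width_min = 5)
  sim <- simulate_tacs(p, g, zero_tac)
  expect_true(all(abs(as.matrix(sim$frames[, 2:4])) < 1e-14))
  expect_identical(mass_balance(sim), 0)
})

test_that("outputs scale linearly with the input pulse", {
  cfg <- synthetic_config(noise_cv = 0)
  pulse <- generate_input_pulse(cfg)
  sim1 <- simulate_tacs(cfg$params, cfg$geom, pulse)
  pulse3 <- pulse
  pulse3$input <- 3 * pulse3$input
  sim3 <- simulate_tacs(cfg$params, cfg$geom, pulse3)
  expect_equal(as.matrix(sim3$frames[, 2:4]),
               3 * as.matrix(sim1$frames[, 2:4]), tolerance = 1e-8)
})

test_that("downstream peak amplitudes strictly decrease along the shoot", {
  cfg <- synthetic_config(noise_cv = 0)
  pulse <- generate_input_pulse(cfg)
  sim <- simulate_tacs(cfg$params, cfg$geom, pulse)
  peaks <- c(max(pulse$input), max(sim$frames$roi1), max(sim$frames$roi2),
             max(sim$frames$roi3))
  expect_true(all(diff(peaks) < 0))
})

test_that("concentrations stay non-negative and storage is monotone", {
  g <- roi_geometry()
  set.seed(7)
  for (rep in 1:5) {
    p <- model_parameters(runif(1, 32, 216), runif(1, 0, 0.5),
                          runif(1, 0, 0.5), runif(1, 0, 0.5))
    pulse <- generate_input_pulse(synthetic_config(params = p, noise_cv = 0))
    sim <- simulate_tacs(p, g, pulse)
    states <- as.matrix(sim$dense[phloempet:::state_names[1:11]])
    expect_true(all(states > -1e-10))
    for (col in c("C3_input", "C3_roi1", "C3_roi2", "C3_roi3"))
      expect_true(all(diff(sim$dense[[col]]) > -1e-12))
  }
})

test_that("adaptive solver agrees with an independent fixed-step Euler oracle", {
  p <- reference_params()
  g <- roi_geometry()
  pulse <- generate_input_pulse(synthetic_config(params = p, noise_cv = 0))
  sim <- simulate_tacs(p, g, pulse)
  oracle <- euler_simulate(p, g, pulse, dt_min = 0.001)
  idx <- match(round(oracle$time_min, 6), round(sim$dense$time_min, 6))
  expect_false(anyNA(idx))
  for (roi in c("roi1", "roi2", "roi3")) {
    got <- sim$dense[[paste0("total_", roi)]][idx]
    expect_lt(max(abs(got - oracle[[roi]])) / max(abs(oracle[[roi]])), 1e-3)
  }
})

test_that("mass balance closes to better than 1e-4 across configurations", {
  g <- roi_geometry()
  grid <- list(reference_params(),
               model_parameters(128, 0, 0, 0),      # pure advection chain
               model_parameters(70, 0.07, 0.25, 0.30),
               model_parameters(200, 0.4, 0, 0.5),  # no storage
               model_parameters(50, 0.3, 0.4, 0))   # no efflux
  for (p in grid) {
    pulse <- generate_input_pulse(synthetic_config(params = p, noise_cv = 0))
    expect_lt(mass_balance(simulate_tacs(p, g, pulse)), 1e-4)
  }
})

test_that("per-frame totals are reproducible from the dense trajectories", {
  cfg <- synthetic_config(noise_cv = 0)
  pulse <- generate_input_pulse(cfg)
  sim <- simulate_tacs(cfg$params, cfg$geom, pulse)
  d <- sim$dense
  w <- 5
  for (i in c(3, 14, 24)) {
    mid <- sim$frames$time_min[i]
    sel <- which(d$time_min >= mid - w / 2 - 1e-9 &
                 d$time_min <= mid + w / 2 + 1e-9)
    tt <- d$time_min[sel]
    y <- d$total_roi2[sel]
    manual <- sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) / (max(tt) - min(tt))
    expect_equal(sim$frames$roi2[i], manual, tolerance = 1e-12)
  }
  # midpoint sampling option
  simm <- simulate_tacs(cfg$params, cfg$geom, pulse, frame_stat = "midpoint")
  i <- 14
  j <- which.min(abs(d$time_min - simm$frames$time_min[i]))
  expect_equal(simm$frames$roi1[i], d$total_roi1[j], tolerance = 1e-9)
})

test_that("initial-condition convention barely affects calibrated-scale outputs", {
  cfg <- synthetic_config(noise_cv = 0)
  pulse <- generate_input_pulse(cfg)
  s1 <- simulate_tacs(cfg$params, cfg$geom, pulse, init = "compartment1")
  s2 <- simulate_tacs(cfg$params, cfg$geom, pulse, init = "distributed")
  # first-frame activity is tiny relative to the pulse, so the outputs
  # are nearly insensitive to how it is distributed
  rel <- max(abs(as.matrix(s1$frames[, 2:4]) - as.matrix(s2$frames[, 2:4]))) /
    max(as.matrix(s1$frames[, 2:4]))
  expect_lt(rel, 0.01)
})

test_that("non-decay-corrected input is refused", {
  cfg <- synthetic_config(noise_cv = 0)
  set <- generate_roi_set(cfg)
  raw <- set$noiseless
  attr(raw, "decay_corrected") <- FALSE
  expect_error(simulate_tacs(cfg$params, cfg$geom, raw), "decay")
})
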