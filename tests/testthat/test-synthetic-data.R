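test_that("input pulse peaks in the frame containing the configured peak time", {
  pulse <- generate_input_pulse(synthetic_config(peak_time_min = 65))
  peak_frame_mid <- pulse$time_min[which.max(pulse$input)]
  expect_gte(peak_frame_mid, 62.5)
  expect_lte(peak_frame_mid, 67.5)

  pulse2 <- generate_input_pulse(synthetic_config(peak_time_min = 40))
  expect_equal(pulse2$time_min[which.max(pulse2$input)], 42.5,
               tolerance = 5)
})

test_that("a larger shape exponent narrows the pulse", {
  widths <- vapply(c(2, 4, 8, 16), function(a) {
    p <- generate_input_pulse(synthetic_config(shape_exponent = a))
    sum(p$input > max(p$input) / 2) * 5  # minutes above half maximum
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the pulse is linear in the amplitude", {
  p1 <- generate_input_pulse(synthetic_config(amplitude = 1))
  p3 <- generate_input_pulse(synthetic_config(amplitude = 3.5))
  expect_equal(p3$input, 3.5 * p1$input, tolerance = 1e-12)
})

test_that("noise generation is seeded, optional, and clipped at zero", {
  cfg0 <- synthetic_config(noise_cv = 0)
  set0 <- generate_roi_set(cfg0, solver = quick_solver())
  expect_identical(set0$noisy, set0$noiseless)

  cfg <- synthetic_config(noise_cv = 0.05, seed = 99)
  s1 <- generate_roi_set(cfg, solver = quick_solver())
  s2 <- generate_roi_set(cfg, solver = quick_solver())
  expect_identical(s1$noisy, s2$noisy)
  expect_false(identical(s1$noisy, s1$noiseless))
  expect_true(all(as.matrix(s1$noisy[, 2:5]) >= 0))

  big <- generate_roi_set(synthetic_config(noise_cv = 2, seed = 1),
                          solver = quick_solver())
  expect_true(all(as.matrix(big$noisy[, 2:5]) >= 0))
})

test_that("empirical noise level matches the configured coefficient of variation", {
  cv <- 0.05
  ratios <- c()
  for (seed in 1:10) {
    set <- generate_roi_set(synthetic_config(noise_cv = cv, seed = seed),
                            solver = quick_solver())
    clean <- as.matrix(set$noiseless[, 2:5])
    noisy <- as.matrix(set$noisy[, 2:5])
    keep <- clean > 0.05 * max(clean)  # well above the zero-clip region
    ratios <- c(ratios, (noisy[keep] - clean[keep]) / clean[keep])
  }
  expect_equal(sd(ratios), cv, tolerance = 0.1)
  expect_lt(abs(mean(ratios)), 0.01)
})

test_that("downstream ROI peaks decrease with ROI index in generated sets", {
  set <- noiseless_set()
  peaks <- vapply(c("input", "roi1", "roi2", "roi3"),
                  function(nm) max(set$noiseless[[nm]]), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("phantom painting round-trips through ROI extraction", {
  cfg <- synthetic_config(noise_cv = 0)
  ph <- generate_phantom_4d(cfg, dims = c(24, 24, 64), voxel_mm = 0.4)
  for (s in 1:4) {
    painted <- ph$tacs[[ph$rois[[s]]$label]]
    extracted <- extract_roi_tac(ph, ph$rois[[s]])
    rel <- max(abs(extracted - painted)) / max(painted)
    expect_lt(rel, 0.02)
  }
})

test_that("an all-zero configuration paints an all-zero volume", {
  cfg <- synthetic_config(amplitude = 1e-300, noise_cv = 0)
  ph <- generate_phantom_4d(cfg, dims = c(16, 16, 48), voxel_mm = 0.5)
  expect_lt(max(abs(ph$volume)), 1e-250)
})

test_that("scanner-resolution blur lowers the apparent peak in a thin stem", {
  cfg <- synthetic_config(noise_cv = 0,
                          geom = roi_geometry(stem_diameter_mm = 1.6))
  sharp <- generate_phantom_4d(cfg, dims = c(24, 24, 64), voxel_mm = 0.4)
  blurred <- generate_phantom_4d(cfg, dims = c(24, 24, 64), voxel_mm = 0.4,
                                 blur_fwhm_mm = 0.8)
  tac_sharp <- extract_roi_tac(sharp, sharp$rois[[1]])
  tac_blur <- extract_roi_tac(blurred, blurred$rois[[1]])
  expect_lt(max(tac_blur), max(tac_sharp))
})

test_that("phantom geometry is validated against the grid", {
  cfg <- synthetic_config(noise_cv = 0,
                          geom = roi_geometry(stem_diameter_mm = 20))
  expect_error(generate_phantom_4d(cfg, dims = c(16, 16, 48)),
               "field of view")
  cfg2 <- synthetic_config(noise_cv = 0,
                           geom = roi_geometry(roi_length_mm = 50))
  expect_error(generate_phantom_4d(cfg2, dims = c(16, 16, 48)), "fit")
})
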