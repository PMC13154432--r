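# Shared fixtures. Expensive objects are memoised in an environment so
# each is built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# literature-magnitude primary-shoot truth
reference_params <- function() model_parameters(128, 0.27, 0.08, 0.38)

# solver used for iterative work in tests: identical model, coarser
# step cap / output grid (agrees with the reference configuration to
# ~2e-5 relative)
quick_solver <- function() solver_control(hmax_min = 0.1, dt_out_min = 0.5)

# noiseless literature-magnitude ROI set, generated with the quick solver so
# that calibration against it is an exact inverse problem
noiseless_set <- function() memo("noiseless_set", {
  generate_roi_set(synthetic_config(params = reference_params(), noise_cv = 0),
                   solver = quick_solver())
})

# one calibrated fit of that set (budget 4500, the standard configuration)
reference_fit <- function() memo("reference_fit", {
  calibrate(noiseless_set()$noiseless, roi_geometry(),
            calibration_config(seed = 101, solver = quick_solver()))
})

# fixed-step explicit-Euler integration of the model equations, written
# directly from phloem_derivatives(); independent of the compiled
# solver path. Returns dense per-ROI totals on a coarse recording grid.
euler_simulate <- function(params, geom, input_tac, dt_min = 0.001,
                           t_end = 120, record_every = 100L) {
  input_fun <- approxfun(input_tac$time_min, input_tac$input, rule = 2)
  state <- setNames(numeric(14), phloempet:::state_names)
  nsteps <- round(t_end / dt_min)
  nrec <- nsteps %/% record_every + 1L
  rec <- matrix(NA_real_, nrow = nrec, ncol = 4,
                dimnames = list(NULL, c("time_min", "roi1", "roi2", "roi3")))
  totals <- function(s)
    c(sum(s[3:5]), sum(s[6:8]), sum(s[9:11]))
  rec[1, ] <- c(0, totals(state))
  r <- 1L
  t <- 0
  for (i in seq_len(nsteps)) {
    state <- state + dt_min *
      phloem_derivatives(t, state, params, geom, input_fun)
    t <- i * dt_min
    if (i %% record_every == 0L) {
      r <- r + 1L
      rec[r, ] <- c(t, totals(state))
    }
  }
  as.data.frame(rec)
}
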