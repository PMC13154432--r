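# Forward simulation of the four-compartment tracer model.
#
# Each ROI i holds three modelled compartments: C1 (sieve tubes, advective
# transport at plug-flow speed s_ph), C2 (phloem parenchyma, exchanging
# with C1 at rates a12 / a21 = h*a12 and feeding C3 and the atmosphere)
# and C3 (irreversible storage). The atmosphere (compartment 4) is tracked
# only as cumulative efflux. The input ROI's C1 is closed algebraically
# against the measured total: C1 = total - C2 - C3, floored at zero.
#
# Exchange fraction rates (a12, a21, b, c) act per minute; the phloem
# front speed is in um/s, so the advective rate s_ph/l (in 1/s) is
# multiplied by 60 where it enters the per-minute dynamics. The internal
# ODE time unit is minutes, matching the frame grid.

#' Advective rate constant of the transport compartment
#'
#' Converts the phloem front speed and the ROI length into the first-order
#' advective exchange rate `s_ph / l` that couples consecutive ROIs.
#' `s_ph` is in um/s and `l` in mm, so the rate is
#' `s_ph / (1000 * l)` per second.
#'
#' @param params A [model_parameters()] object.
#' @param geom A [roi_geometry()] object.
#' @return Advective rate constant, 1/s.
#' @examples
#' advective_rate_constant(model_parameters(128, 0.27, 0.08, 0.38),
#'                         roi_geometry())  # 128/(4*1000) = 0.032
#' @export
advective_rate_constant <- function(params, geom) {
  stopifnot(inherits(params, "phloem_params"), inherits(geom, "roi_geometry"))
  params$s_ph / (1000 * geom$roi_length_mm)
}

#' Algebraic closure of the input ROI's transport compartment
#'
#' The input ROI receives tracer from outside the modelled chain, so its
#' transport-compartment concentration is derived from the measured total
#' rather than integrated: `C1 = total - C2 - C3`. Measurement noise can
#' drive the difference negative, in which case it is floored at zero.
#'
#' @param total_measured Measured total concentration of the input ROI,
#'   MBq/mL (interpolated at the requested time).
#' @param c2_input,c3_input Current simulated concentrations of the input
#'   ROI's transient-storage and storage compartments, MBq/mL.
#' @return The input ROI's transport-compartment concentration, >= 0.
#' @export
input_c1 <- function(total_measured, c2_input, c3_input) {
  pmax(total_measured - c2_input - c3_input, 0)
}

state_names <- c("C2_input", "C3_input",
                 "C1_roi1", "C2_roi1", "C3_roi1",
                 "C1_roi2", "C2_roi2", "C3_roi2",
                 "C1_roi3", "C2_roi3", "C3_roi3",
                 "cum_inflow", "cum_efflux", "cum_outflow")

#' Time derivative of the model state
#'
#' Evaluates the right-hand side of the compartmental balance equations at
#' one time point. This is the reference R implementation of the model
#' equations; [simulate_tacs()] integrates an equivalent compiled version.
#'
#' @param t Time, minutes.
#' @param state Named numeric vector in the order given by
#'   `phloempet:::state_names`: C2/C3 of the input ROI, C1/C2/C3 of ROIs
#'   1-3, and three cumulative bookkeeping integrals (advective inflow to
#'   ROI 1, efflux from ROIs 1-3, advective outflow from ROI 3).
#' @param params A [model_parameters()] object.
#' @param geom A [roi_geometry()] object.
#' @param input_fun Function of time (minutes) returning the measured
#'   total concentration of the input ROI.
#' @return Named vector of derivatives, per-minute scale.
#' @export
phloem_derivatives <- function(t, state, params, geom, input_fun) {
  if (length(state) != length(state_names))
    stop(sprintf("state must have %d components, got %d",
                 length(state_names), length(state)), call. = FALSE)
  k <- 60 * advective_rate_constant(params, geom)  # per minute
  a12 <- params$a12; ret <- params$a21
  loss <- ret + params$b + params$c
  c1_in <- input_c1(input_fun(t), state[1], state[2])

  d <- numeric(length(state))
  d[1] <- a12 * c1_in - loss * state[1]
  d[2] <- params$b * state[1]
  upstream <- c1_in
  for (i in 0:2) {
    c1 <- state[3 + 3 * i]; c2 <- state[4 + 3 * i]
    d[3 + 3 * i] <- k * upstream - k * c1 - a12 * c1 + ret * c2
    d[4 + 3 * i] <- a12 * c1 - loss * c2
    d[5 + 3 * i] <- params$b * c2
    upstream <- c1
  }
  d[12] <- k * c1_in
  d[13] <- params$c * (state[4] + state[7] + state[10])
  d[14] <- k * state[9]
  setNames(d, state_names)
}

#' Solver settings for the forward simulation
#'
#' Defaults follow the adaptive fourth-order Runge-Kutta configuration
#' used for model calibration in this field: tolerance 1e-5 and a maximum
#' step of 0.01 min. `dt_out_min` controls the dense output grid from
#' which per-frame averages are computed.
#'
#' @param method A `deSolve` integration method; the default
#'   `"rk45dp7"` is the adaptive Dormand-Prince 4(5) pair.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param hmax_min Maximum internal step size, minutes.
#' @param dt_out_min Dense output spacing, minutes; must divide the frame
#'   width.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(method = "rk45dp7", rtol = 1e-5, atol = 1e-9,
                           hmax_min = 0.01, dt_out_min = 0.1) {
  stopifnot(rtol > 0, atol > 0, hmax_min > 0, dt_out_min > 0)
  structure(list(method = method, rtol = rtol, atol = atol,
                 hmax_min = hmax_min, dt_out_min = dt_out_min),
            class = "solver_control")
}

input_forcing <- function(input_tac) {
  cbind(input_tac$time_min, input_tac$input)
}

#' Simulate the tracer concentrations of a ROI set
#'
#' Integrates the four-compartment model over the acquisition window,
#' driven by the measured (or synthetic) input-ROI TAC. The input TAC is
#' interpolated piecewise-linearly between frame midpoints and held
#' constant outside them. At the start of the simulation all measured
#' tracer is assumed to sit in compartment 1 of the input ROI
#' (`init = "compartment1"`); `init = "distributed"` spreads the initial
#' activity equally over the input ROI's three compartments instead.
#'
#' @param params A [model_parameters()] object.
#' @param geom A [roi_geometry()] object.
#' @param input_tac A [tac_table()] (only the `input` column is used) or a
#'   data.frame with columns `time_min` and `input`.
#' @param t_span Simulation window in minutes, `c(from, to)`. Defaults to
#'   frame edges spanning the input TAC (`0` to last midpoint + half a
#'   frame).
#' @param solver A [solver_control()] object.
#' @param init Initial-condition convention, `"compartment1"` or
#'   `"distributed"`.
#' @param frame_stat How dense trajectories are reduced to per-frame
#'   values for comparison with PET data: `"average"` (trapezoidal mean
#'   over each frame window, matching how PET frames are acquired) or
#'   `"midpoint"` (point sample at the frame midpoint).
#'
#' @return An object of class `phloem_sim`: a list with
#'   \describe{
#'     \item{dense}{data.frame of the dense trajectories (time in min,
#'       every compartment, per-ROI totals, and the interpolated input).}
#'     \item{frames}{data.frame of per-frame ROI totals on the input
#'       TAC's time grid.}
#'     \item{balance}{cumulative inflow, efflux, outflow and stored
#'       activity for the mass-balance audit.}
#'     \item{params, geom, solver, init, frame_stat}{the call's inputs.}
#'   }
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' pulse <- generate_input_pulse(cfg)
#' sim <- simulate_tacs(cfg$params, cfg$geom, pulse)
#' head(sim$frames)
#' @export
simulate_tacs <- function(params, geom, input_tac, t_span = NULL,
                          solver = solver_control(),
                          init = c("compartment1", "distributed"),
                          frame_stat = c("average", "midpoint")) {
  stopifnot(inherits(params, "phloem_params"), inherits(geom, "roi_geometry"))
  init <- match.arg(init)
  frame_stat <- match.arg(frame_stat)
  if (!all(c("time_min", "input") %in% names(input_tac)))
    stop("'input_tac' needs columns 'time_min' and 'input'", call. = FALSE)
  if (inherits(input_tac, "tac_table") &&
      !isTRUE(attr(input_tac, "decay_corrected")))
    stop("input TAC must be decay-corrected: the model has no decay term",
         call. = FALSE)

  w <- frame_width(input_tac)
  if (is.null(t_span)) {
    t_span <- c(max(0, input_tac$time_min[1] - w / 2),
                input_tac$time_min[nrow(input_tac)] + w / 2)
  }
  dt <- solver$dt_out_min
  times_min <- seq(t_span[1], t_span[2], by = dt)
  if (abs(times_min[length(times_min)] - t_span[2]) > 1e-9)
    stop("'dt_out_min' must divide the simulation span", call. = FALSE)

  y0 <- setNames(numeric(length(state_names)), state_names)
  if (init == "distributed") {
    total0 <- input_tac$input[1]  # constant extrapolation before first frame
    y0["C2_input"] <- total0 / 3
    y0["C3_input"] <- total0 / 3
  }

  parms <- c(k = 60 * advective_rate_constant(params, geom),
             a12 = params$a12, h = params$h, b = params$b,
             c = params$c)
  method <- if (identical(solver$method, "rk45dp7"))
    deSolve::rkMethod("rk45dp7") else solver$method

  out <- deSolve::ode(
    y = y0, times = times_min, func = "phloem_derivs",
    parms = parms, dllname = "phloempet", initfunc = "phloem_initmod",
    initforc = "phloem_initforc", forcings = input_forcing(input_tac),
    fcontrol = list(method = "linear", rule = 2),
    nout = 1, outnames = "C1_input",
    method = method, rtol = solver$rtol, atol = solver$atol,
    hmax = solver$hmax_min
  )
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times_min)) {
    last_t <- out[nrow(out), "time"]
    stop(sprintf("ODE solver failed at t = %.3f min", last_t), call. = FALSE)
  }

  dense <- as.data.frame(out)
  dense$time_min <- dense$time
  dense$total_input <- approx(input_tac$time_min, input_tac$input,
                              xout = dense$time_min, rule = 2)$y
  for (i in 1:3) {
    dense[[paste0("total_roi", i)]] <-
      dense[[paste0("C1_roi", i)]] + dense[[paste0("C2_roi", i)]] +
      dense[[paste0("C3_roi", i)]]
  }

  frames <- frame_totals(dense, input_tac$time_min, w, frame_stat)
  stored <- sum(dense[nrow(dense),
                      c("C1_roi1", "C2_roi1", "C3_roi1",
                        "C1_roi2", "C2_roi2", "C3_roi2",
                        "C1_roi3", "C2_roi3", "C3_roi3")])
  balance <- list(
    inflow = dense$cum_inflow[nrow(dense)],
    efflux = dense$cum_efflux[nrow(dense)],
    outflow = dense$cum_outflow[nrow(dense)],
    stored = stored
  )

  structure(list(dense = dense, frames = frames, balance = balance,
                 params = params, geom = geom, solver = solver,
                 init = init, frame_stat = frame_stat),
            class = "phloem_sim")
}

# Reduce dense per-ROI totals to one value per frame. Frames are the
# windows [t - w/2, t + w/2] around each midpoint t; "average" integrates
# the dense trajectory with the trapezoidal rule over the window.
frame_totals <- function(dense, mid_min, w, frame_stat) {
  cols <- paste0("total_roi", 1:3)
  res <- matrix(NA_real_, nrow = length(mid_min), ncol = 3,
                dimnames = list(NULL, cols))
  if (frame_stat == "midpoint") {
    for (j in cols)
      res[, j] <- approx(dense$time_min, dense[[j]], xout = mid_min,
                         rule = 2)$y
  } else {
    t <- dense$time_min
    for (i in seq_along(mid_min)) {
      lo <- max(mid_min[i] - w / 2, t[1])
      hi <- min(mid_min[i] + w / 2, t[length(t)])
      sel <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
      tt <- t[sel]
      for (j in cols) {
        y <- dense[[j]][sel]
        res[i, j] <- sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) /
          (tt[length(tt)] - tt[1])
      }
    }
  }
  data.frame(time_min = mid_min, roi1 = res[, 1], roi2 = res[, 2],
             roi3 = res[, 3])
}

# --- lean simulation path for iterative fitting -------------------------
#
# The calibration objective only needs the per-frame ROI totals, so the
# dense data.frame bookkeeping of simulate_tacs() is skipped. The
# context pre-computes everything that does not depend on the parameters
# (output grid, forcing table, initial state, trapezoidal frame-
# aggregation weights); sim_frames_fast() then returns a frames x 3
# matrix of ROI totals.

make_sim_context <- function(observed, geom, solver = solver_control(),
                             frame_stat = "average") {
  w <- frame_width(observed)
  t_span <- c(max(0, observed$time_min[1] - w / 2),
              observed$time_min[nrow(observed)] + w / 2)
  dt <- solver$dt_out_min
  times_min <- seq(t_span[1], t_span[2], by = dt)
  npts <- length(times_min)
  nfr <- nrow(observed)
  A <- matrix(0, nrow = nfr, ncol = npts)
  if (frame_stat == "midpoint") {
    for (i in seq_len(nfr)) {
      j <- which.min(abs(times_min - observed$time_min[i]))
      A[i, j] <- 1
    }
  } else {
    for (i in seq_len(nfr)) {
      lo <- max(observed$time_min[i] - w / 2, times_min[1])
      hi <- min(observed$time_min[i] + w / 2, times_min[npts])
      sel <- which(times_min >= lo - 1e-9 & times_min <= hi + 1e-9)
      wt <- rep(dt, length(sel))
      wt[c(1, length(sel))] <- dt / 2
      A[i, sel] <- wt / (hi - lo)
    }
  }
  method <- if (identical(solver$method, "rk45dp7"))
    deSolve::rkMethod("rk45dp7") else solver$method
  list(times_min = times_min,
       forcings = input_forcing(observed),
       y0 = setNames(numeric(length(state_names)), state_names),
       A = A, geom = geom, solver = solver, method = method)
}

sim_frames_fast <- function(params, ctx) {
  parms <- c(k = 60 * advective_rate_constant(params, ctx$geom),
             a12 = params$a12, h = params$h, b = params$b, c = params$c)
  out <- deSolve::ode(
    y = ctx$y0, times = ctx$times_min, func = "phloem_derivs",
    parms = parms, dllname = "phloempet", initfunc = "phloem_initmod",
    initforc = "phloem_initforc", forcings = ctx$forcings,
    fcontrol = list(method = "linear", rule = 2),
    nout = 1, outnames = "C1_input",
    method = ctx$method, rtol = ctx$solver$rtol, atol = ctx$solver$atol,
    hmax = ctx$solver$hmax_min
  )
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(ctx$times_min))
    stop("ODE solver failed", call. = FALSE)
  totals <- cbind(out[, "C1_roi1"] + out[, "C2_roi1"] + out[, "C3_roi1"],
                  out[, "C1_roi2"] + out[, "C2_roi2"] + out[, "C3_roi2"],
                  out[, "C1_roi3"] + out[, "C2_roi3"] + out[, "C3_roi3"])
  ctx$A %*% totals
}

#' @export
print.phloem_sim <- function(x, ...) {
  cat(sprintf("Four-compartment simulation: %d dense points, %d frames\n",
              nrow(x$dense), nrow(x$frames)))
  cat(sprintf("  mass-balance residual: %.2e\n", mass_balance(x)))
  invisible(x)
}

#' Mass-balance audit of a simulation
#'
#' The model conserves tracer: everything that enters ROI 1 by advection
#' is, at any later time, either stored in ROIs 1-3, lost to the
#' atmosphere, or advected out of ROI 3. This returns the relative
#' closure error `|stored + efflux + outflow - inflow| / inflow`
#' (0 by convention when nothing flowed in), a direct audit of solver
#' fidelity.
#'
#' @param sim A `phloem_sim` object from [simulate_tacs()].
#' @return Dimensionless residual.
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "phloem_sim"))
  b <- sim$balance
  if (b$inflow <= 0) return(0)
  abs(b$stored + b$efflux + b$outflow - b$inflow) / b$inflow
}
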