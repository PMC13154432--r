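# Local sensitivity analysis and collinearity-index identifiability.
#
# Two sensitivity surfaces are supported. "states" differentiates every
# modelled compartment trajectory on a dense time grid -- this is how
# plant-modelling tools assess structural identifiability, and it
# reproduces the collinearity indices reported for this model (roughly 5
# to 15 at literature-magnitude parameters). "observed" differentiates
# only the frame-aggregated ROI totals that the calibration objective
# can see; it is far worse conditioned (gamma in the hundreds), which is
# why per-fit parameter uncertainty under measurement noise is much
# larger than the state-level analysis suggests.

#' Relative sensitivities of the model outputs to the parameters
#'
#' Central finite differences of the model outputs with respect to each
#' free parameter, scaled by the parameter value and normalized by the
#' output, giving dimensionless relative sensitivities. Parameters on a
#' bound fall back to a one-sided difference with a warning.
#'
#' @param params [model_parameters()] at which to linearize (typically a
#'   calibrated fit).
#' @param geom [roi_geometry()].
#' @param input_tac Input TAC (a [tac_table()] or a `time_min`/`input`
#'   data.frame).
#' @param free Parameters to differentiate, a subset of
#'   `c("s_ph", "a12", "b", "c", "h")`.
#' @param surface `"states"` (default): every compartment trajectory
#'   sampled every `dt_state_min` minutes; `"observed"`: the
#'   frame-aggregated totals of ROIs 1-3, i.e. the data surface of
#'   [rmse_objective()].
#' @param normalization `"relative"` (default): each output point is
#'   scaled by its own baseline magnitude, floored at 1% of the largest
#'   baseline value to keep early near-zero points finite; `"rms"`: all
#'   points are scaled by the root mean square of the baseline output.
#' @param rel_step Relative finite-difference step (default 1e-4), with
#'   an absolute floor of 1e-8 for near-zero parameters.
#' @param bounds Bounds used to detect boundary parameters.
#' @param solver [solver_control()].
#' @param dt_state_min Sampling interval of the state surface, minutes.
#' @return A matrix of class `sensitivity_matrix` with one row per
#'   output point and one column per parameter; attributes record the
#'   surface, the normalization and the steps used.
#' @export
relative_sensitivities <- function(params, geom, input_tac,
                                   free = c("s_ph", "a12", "b", "c"),
                                   surface = c("states", "observed"),
                                   normalization = c("relative", "rms"),
                                   rel_step = 1e-4,
                                   bounds = default_bounds(),
                                   solver = solver_control(),
                                   dt_state_min = 1) {
  stopifnot(inherits(params, "phloem_params"), inherits(geom, "roi_geometry"))
  free <- match.arg(free, PARAM_ORDER, several.ok = TRUE)
  surface <- match.arg(surface)
  normalization <- match.arg(normalization)

  model_surface <- function(p) {
    sim <- simulate_tacs(p, geom, input_tac, solver = solver)
    if (surface == "observed") {
      as.numeric(as.matrix(sim$frames[c("roi1", "roi2", "roi3")]))
    } else {
      d <- sim$dense
      stride <- max(1L, round(dt_state_min / solver$dt_out_min))
      rows <- seq(1L, nrow(d), by = stride)
      unlist(d[rows, setdiff(state_names,
                             c("cum_inflow", "cum_efflux", "cum_outflow"))],
             use.names = FALSE)
    }
  }
  vals <- c(s_ph = params$s_ph, a12 = params$a12, b = params$b,
            c = params$c, h = params$h)
  y0 <- model_surface(params)
  ymax <- max(abs(y0))
  if (ymax == 0)
    stop("baseline output is identically zero; sensitivities undefined",
         call. = FALSE)
  denom <- if (normalization == "relative") pmax(abs(y0), 0.01 * ymax)
           else rep(sqrt(mean(y0^2)), length(y0))

  S <- matrix(NA_real_, nrow = length(y0), ncol = length(free),
              dimnames = list(NULL, free))
  steps <- numeric(length(free))
  perturbed <- function(nm, value) {
    v <- vals
    v[nm] <- value
    model_parameters(v[["s_ph"]], v[["a12"]], v[["b"]], v[["c"]], v[["h"]])
  }
  for (j in seq_along(free)) {
    nm <- free[j]
    th <- vals[[nm]]
    delta <- max(rel_step * abs(th), 1e-8)
    b <- bounds[[nm]]
    lo_ok <- is.null(b) || th - delta >= b[1]
    hi_ok <- is.null(b) || th + delta <= b[2]
    if (lo_ok && hi_ok) {
      dy <- (model_surface(perturbed(nm, th + delta)) -
             model_surface(perturbed(nm, th - delta))) / (2 * delta)
    } else if (hi_ok) {
      warning(sprintf("parameter '%s' is on its lower bound; using one-sided difference", nm),
              call. = FALSE)
      dy <- (model_surface(perturbed(nm, th + delta)) - y0) / delta
    } else {
      warning(sprintf("parameter '%s' is on its upper bound; using one-sided difference", nm),
              call. = FALSE)
      dy <- (y0 - model_surface(perturbed(nm, th - delta))) / delta
    }
    S[, j] <- dy * th / denom
    steps[j] <- delta
  }
  structure(S, class = c("sensitivity_matrix", "matrix"),
            surface = surface, normalization = normalization,
            rel_step = rel_step, steps = setNames(steps, free))
}

#' Collinearity index of a parameter subset
#'
#' `gamma = 1 / sqrt(lambda_min(S~' S~))` where `S~` holds the subset's
#' unit-normalized sensitivity columns. `gamma = 1` for orthonormal
#' columns; exactly collinear columns give `gamma = Inf`. Subsets of
#' size 1 with a non-degenerate column return 1 by convention.
#'
#' @param S A [relative_sensitivities()] matrix (or any numeric matrix
#'   with named columns).
#' @param subset Column names (or indices) of the subset; defaults to all
#'   columns.
#' @return The collinearity index, a scalar >= 1 (possibly `Inf`).
#' @export
collinearity_index <- function(S, subset = colnames(S)) {
  M <- S[, subset, drop = FALSE]
  if (ncol(M) == 0) stop("subset must be non-empty", call. = FALSE)
  norms <- sqrt(colSums(M^2))
  if (any(norms == 0)) return(Inf)
  Sn <- sweep(M, 2, norms, "/")
  lam <- eigen(crossprod(Sn), symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(lam)
  if (lmin <= .Machine$double.eps) return(Inf)
  1 / sqrt(lmin)
}

#' Identifiability report over parameter subsets
#'
#' Computes the collinearity index for the full free-parameter set and
#' every subset of size >= 2, flagging each as identifiable when gamma
#' stays below the threshold (subsets with gamma above it are deemed
#' unidentifiable).
#'
#' @inheritParams relative_sensitivities
#' @param threshold Identifiability threshold on gamma (default 15).
#' @param S Optional precomputed [relative_sensitivities()] matrix; when
#'   supplied, `params`, `geom` and `input_tac` are ignored.
#' @param ... Further arguments passed to [relative_sensitivities()].
#' @return An object of class `identifiability_report`: a data.frame
#'   with columns `subset`, `size`, `gamma`, `identifiable`, plus
#'   attributes `threshold`, `surface` and `normalization`.
#' @export
assess_identifiability <- function(params = NULL, geom = NULL,
                                   input_tac = NULL,
                                   free = c("s_ph", "a12", "b", "c"),
                                   threshold = 15, S = NULL,
                                   solver = solver_control(), ...) {
  if (is.null(S))
    S <- relative_sensitivities(params, geom, input_tac, free = free,
                                solver = solver, ...)
  nms <- colnames(S)
  subsets <- list()
  for (size in c(if (length(nms) > 1) 2:length(nms) else 1))
    subsets <- c(subsets, combn(nms, size, simplify = FALSE))
  rows <- lapply(subsets, function(ss) {
    g <- collinearity_index(S, ss)
    data.frame(subset = paste(ss, collapse = ","), size = length(ss),
               gamma = g, identifiable = is.finite(g) && g < threshold)
  })
  rep <- do.call(rbind, rows)
  structure(rep, threshold = threshold,
            surface = attr(S, "surface"),
            normalization = attr(S, "normalization"),
            class = c("identifiability_report", "data.frame"))
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(sprintf("Collinearity-index identifiability (threshold %g, surface: %s, normalization: %s)\n",
              attr(x, "threshold"),
              attr(x, "surface") %||% "?", attr(x, "normalization") %||% "?"))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
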