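#' Transport parameters of the four-compartment phloem model
#'
#' Bundles the calibrated quantities of the tracer model: the phloem front
#' speed `s_ph` (plug-flow speed of the fastest tracer particles in the
#' sieve tubes), the unloading exchange fraction rate `a12` (sieve tubes to
#' phloem parenchyma), the storage rate `b` (parenchyma to the immobilizing
#' storage compartment), the efflux rate `c` (parenchyma to the atmosphere,
#' respiratory CO2 loss) and the dimensionless coupling constant `h` that
#' ties the retrieval rate to the unloading rate, `a21 = h * a12`.
#' `a21` is always derived, never set independently. Exchange fraction
#' rates are expressed per minute (see the package vignette for why this
#' is the coherent unit at the 5-min-frame / 2-h-scan scale); the phloem
#' front speed is in um/s.
#'
#' @param s_ph Phloem front speed, um/s. Must be positive.
#' @param a12 Unloading exchange fraction rate, per minute, in \[0, 1\].
#' @param b Storage exchange fraction rate, per minute, in \[0, 1\].
#' @param c Efflux exchange fraction rate, per minute, in \[0, 1\].
#' @param h Dimensionless retrieval/unloading coupling constant in (0, 1].
#'   The default 0.68759 is the average of calibrated values from fits in
#'   which `h` was identifiable.
#'
#' @return An object of class `phloem_params`: a named list with elements
#'   `s_ph`, `a12`, `b`, `c`, `h` and the derived `a21`.
#' @examples
#' p <- model_parameters(s_ph = 128, a12 = 0.27, b = 0.08, c = 0.38)
#' p$a21  # h * a12
#' @export
model_parameters <- function(s_ph, a12, b, c, h = 0.68759) {
  stopifnot(is.numeric(s_ph), is.numeric(a12), is.numeric(b),
            is.numeric(c), is.numeric(h))
  if (!is.finite(s_ph) || s_ph <= 0)
    stop("'s_ph' must be a positive phloem front speed in um/s", call. = FALSE)
  for (nm in c("a12", "b", "c")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a fraction rate in [0, 1] per minute", nm),
           call. = FALSE)
  }
  if (!is.finite(h) || h <= 0 || h > 1)
    stop("'h' must lie in (0, 1]", call. = FALSE)
  structure(
    list(s_ph = s_ph, a12 = a12, b = b, c = c, h = h, a21 = h * a12),
    class = "phloem_params"
  )
}

#' @export
print.phloem_params <- function(x, ...) {
  cat("Four-compartment phloem transport parameters\n")
  cat(sprintf("  s_ph : %8.3f um/s  (phloem front speed)\n", x$s_ph))
  cat(sprintf("  a12  : %8.4f 1/min (unloading)\n", x$a12))
  cat(sprintf("  a21  : %8.4f 1/min (retrieval = h * a12)\n", x$a21))
  cat(sprintf("  b    : %8.4f 1/min (storage)\n", x$b))
  cat(sprintf("  c    : %8.4f 1/min (efflux)\n", x$c))
  cat(sprintf("  h    : %8.5f       (coupling constant)\n", x$h))
  invisible(x)
}

#' Geometry of a set of consecutive cylindrical ROIs along a shoot
#'
#' A ROI set consists of four consecutive cylindrical regions of interest
#' along the direction of phloem flow: the input ROI (most proximal to the
#' rosette, index 0) and three downstream ROIs (indices 1-3). All ROIs in
#' a set share the same length `l`, which enters the model through the
#' advective rate constant `s_ph / l`.
#'
#' @param roi_length_mm ROI length in mm. Defaults to 4 mm for primary
#'   shoots and 10 mm for secondary shoots.
#' @param shoot_class `"primary"` or `"secondary"`.
#' @param position_cm Optional distance of the ROI-set midpoint above the
#'   rosette, cm.
#' @param stem_diameter_mm Optional stem diameter, mm.
#'
#' @return An object of class `roi_geometry`.
#' @examples
#' roi_geometry()                        # primary shoot, l = 4 mm
#' roi_geometry(shoot_class = "secondary")  # l = 10 mm
#' @export
roi_geometry <- function(roi_length_mm = NULL,
                         shoot_class = c("primary", "secondary"),
                         position_cm = NULL,
                         stem_diameter_mm = NULL) {
  shoot_class <- match.arg(shoot_class)
  if (is.null(roi_length_mm))
    roi_length_mm <- if (shoot_class == "primary") 4 else 10
  if (!is.numeric(roi_length_mm) || !is.finite(roi_length_mm) ||
      roi_length_mm <= 0)
    stop("'roi_length_mm' must be a positive length in mm", call. = FALSE)
  if (!is.null(stem_diameter_mm) && stem_diameter_mm <= 0)
    stop("'stem_diameter_mm' must be positive", call. = FALSE)
  structure(
    list(roi_length_mm = roi_length_mm, n_rois = 4L,
         shoot_class = shoot_class, position_cm = position_cm,
         stem_diameter_mm = stem_diameter_mm),
    class = "roi_geometry"
  )
}

#' @export
print.roi_geometry <- function(x, ...) {
  cat(sprintf("ROI set on a %s shoot: 4 consecutive ROIs of length %g mm\n",
              x$shoot_class, x$roi_length_mm))
  if (!is.null(x$position_cm))
    cat(sprintf("  midpoint %g cm above the rosette\n", x$position_cm))
  if (!is.null(x$stem_diameter_mm))
    cat(sprintf("  stem diameter %g mm\n", x$stem_diameter_mm))
  invisible(x)
}

#' Time-activity curve table for one ROI set
#'
#' Holds the decay-corrected, per-frame mean tracer concentrations
#' (MBq/mL) of the input ROI and the three downstream ROIs. Times are
#' frame midpoints in minutes post labelling; the default acquisition is
#' 24 frames of 5 min spanning 120 min.
#'
#' @param time_min Frame midpoint times, minutes, strictly increasing.
#' @param input,roi1,roi2,roi3 Concentrations per frame, MBq/mL.
#' @param frame_width_min Frame duration, minutes.
#' @param decay_corrected Logical; must be `TRUE` for modelling (the
#'   kinetic model carries no radioactive-decay term).
#'
#' @return A `data.frame` of class `tac_table` with attributes
#'   `frame_width_min` and `decay_corrected`.
#' @export
tac_table <- function(time_min, input, roi1, roi2, roi3,
                      frame_width_min = 5, decay_corrected = TRUE) {
  n <- length(time_min)
  if (n < 2) stop("a TAC table needs at least two frames", call. = FALSE)
  for (nm in c("input", "roi1", "roi2", "roi3")) {
    v <- get(nm)
    if (length(v) != n)
      stop(sprintf("column '%s' has %d values but there are %d frames",
                   nm, length(v), n), call. = FALSE)
    if (anyNA(v) || any(!is.finite(v)))
      stop(sprintf("column '%s' contains non-finite values", nm),
           call. = FALSE)
  }
  bad <- which(diff(time_min) <= 0)
  if (length(bad))
    stop(sprintf("frame times must be strictly increasing; first violation at row %d (t = %g min)",
                 bad[1] + 1, time_min[bad[1] + 1]), call. = FALSE)
  if (frame_width_min <= 0)
    stop("'frame_width_min' must be positive", call. = FALSE)
  structure(
    data.frame(time_min = time_min, input = input,
               roi1 = roi1, roi2 = roi2, roi3 = roi3),
    frame_width_min = frame_width_min,
    decay_corrected = isTRUE(decay_corrected),
    class = c("tac_table", "data.frame")
  )
}

#' @export
print.tac_table <- function(x, ...) {
  cat(sprintf("Time-activity curves: %d frames of %g min%s\n",
              nrow(x), attr(x, "frame_width_min"),
              if (isTRUE(attr(x, "decay_corrected"))) ", decay-corrected" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

frame_width <- function(tac) {
  w <- attr(tac, "frame_width_min")
  if (is.null(w)) w <- diff(tac$time_min[1:2])
  w
}

scale_tac <- function(tac, kappa) {
  out <- tac
  for (nm in c("input", "roi1", "roi2", "roi3")) out[[nm]] <- kappa * out[[nm]]
  out
}
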