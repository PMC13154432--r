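# Synthetic-data generator: stands in for the PET scanner so that every
# downstream stage (fitting, identifiability, summaries) is testable
# without any acquisition. The input pulse is a gamma-variate bolus, the
# downstream ROIs come from the forward model itself, and measurement
# noise is multiplicative Gaussian with an additive floor.

#' Configuration of a synthetic ROI-set acquisition
#'
#' Describes the ground truth used to generate synthetic time-activity
#' curves: the true transport parameters, the ROI geometry, the shape of
#' the gamma-variate input pulse, the noise model and the frame grid.
#' Defaults emulate a primary-shoot acquisition: literature-magnitude transport
#' parameters, a pulse peaking 65 min post labelling, and 24 frames of
#' 5 min.
#'
#' @param params True [model_parameters()].
#' @param geom [roi_geometry()] of the ROI set.
#' @param peak_time_min Time of the input pulse maximum, minutes post
#'   labelling. Activity peaks around 65-70 min in this system.
#' @param shape_exponent Gamma-variate shape exponent alpha; larger values
#'   give a narrower pulse.
#' @param amplitude Pulse maximum, MBq/mL.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   Gaussian measurement noise (sd = cv * value + floor).
#' @param noise_floor Additive noise floor, MBq/mL.
#' @param n_frames,frame_width_min Frame grid; defaults 24 x 5 min.
#' @param seed Integer seed controlling the noise draws.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(params = model_parameters(128, 0.27, 0.08, 0.38),
                             geom = roi_geometry(),
                             peak_time_min = 65, shape_exponent = 4,
                             amplitude = 1, noise_cv = 0.05,
                             noise_floor = 0, n_frames = 24,
                             frame_width_min = 5, seed = 1L) {
  stopifnot(inherits(params, "phloem_params"), inherits(geom, "roi_geometry"))
  span <- n_frames * frame_width_min
  if (peak_time_min <= 0 || peak_time_min >= span)
    stop("'peak_time_min' must fall inside the frame span", call. = FALSE)
  if (amplitude <= 0) stop("'amplitude' must be positive", call. = FALSE)
  if (noise_cv < 0 || noise_floor < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  structure(
    list(params = params, geom = geom, peak_time_min = peak_time_min,
         shape_exponent = shape_exponent, amplitude = amplitude,
         noise_cv = noise_cv, noise_floor = noise_floor,
         n_frames = as.integer(n_frames),
         frame_width_min = frame_width_min, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

gamma_variate <- function(t, peak, alpha, amplitude) {
  ifelse(t <= 0, 0, amplitude * (t / peak)^alpha * exp(alpha * (1 - t / peak)))
}

#' Generate the synthetic input-ROI pulse
#'
#' Evaluates a gamma-variate bolus
#' `A * (t/tp)^alpha * exp(alpha * (1 - t/tp))` as per-frame averages on
#' the configured frame grid, emulating the pulse-shaped TAC of the input
#' ROI after pulse labelling.
#'
#' @param cfg A [synthetic_config()].
#' @return A data.frame with columns `time_min` (frame midpoints) and
#'   `input` (frame-averaged concentrations, MBq/mL), carrying a
#'   `frame_width_min` attribute.
#' @export
generate_input_pulse <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  w <- cfg$frame_width_min
  edges <- seq(0, cfg$n_frames * w, by = w)
  # frame average by composite trapezoid on a fine sub-grid
  nsub <- 100L
  vals <- vapply(seq_len(cfg$n_frames), function(i) {
    tt <- seq(edges[i], edges[i + 1], length.out = nsub + 1)
    y <- gamma_variate(tt, cfg$peak_time_min, cfg$shape_exponent,
                       cfg$amplitude)
    sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) / w
  }, numeric(1))
  structure(
    data.frame(time_min = (edges[-1] + edges[-length(edges)]) / 2,
               input = vals),
    frame_width_min = w
  )
}

#' Generate a synthetic ROI set (noiseless and noisy TAC tables)
#'
#' Drives the forward model with the synthetic input pulse and the true
#' parameters, yielding a noiseless TAC table, then adds mean-zero
#' multiplicative Gaussian noise (sd = `noise_cv` * value +
#' `noise_floor`, clipped at zero) to every column for the noisy copy.
#'
#' @param cfg A [synthetic_config()].
#' @param solver A [solver_control()] passed to [simulate_tacs()].
#' @return A list of class `synthetic_roi_set` with elements `noiseless`
#'   and `noisy` (both [tac_table()]s), `truth` (the true parameters),
#'   and `cfg`.
#' @export
generate_roi_set <- function(cfg, solver = solver_control()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  pulse <- generate_input_pulse(cfg)
  sim <- simulate_tacs(cfg$params, cfg$geom, pulse, solver = solver)
  clean <- tac_table(pulse$time_min, pulse$input,
                     sim$frames$roi1, sim$frames$roi2, sim$frames$roi3,
                     frame_width_min = cfg$frame_width_min)
  noisy <- clean
  if (cfg$noise_cv > 0 || cfg$noise_floor > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(cfg$seed)
    for (nm in c("input", "roi1", "roi2", "roi3")) {
      v <- clean[[nm]]
      noisy[[nm]] <- pmax(v + rnorm(length(v),
                                    sd = cfg$noise_cv * v + cfg$noise_floor),
                          0)
    }
  }
  structure(list(noiseless = clean, noisy = noisy, truth = cfg$params,
                 cfg = cfg),
            class = "synthetic_roi_set")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Paint a synthetic 4D PET phantom of a stem with consecutive ROIs
#'
#' Voxelizes an axial stem cylinder into a 4D grid and paints, per frame,
#' the concentrations of the four consecutive ROI segments (input + 3)
#' produced by [generate_roi_set()]. Optionally blurs each frame with an
#' isotropic Gaussian to mimic finite scanner resolution. The matching
#' [cylindrical_roi()] definitions are returned so that
#' [extract_roi_tac()] can round-trip the painted values.
#'
#' @param cfg A [synthetic_config()]; the stem diameter defaults to
#'   1.6 mm when the geometry does not specify one.
#' @param dims Grid dimensions in voxels, `c(nx, ny, nz)`. The full
#'   scanner grid is `c(192, 192, 384)`; the default here is a cropped
#'   grid that comfortably contains four ROIs.
#' @param voxel_mm Isotropic voxel size, mm (scanner default 0.4).
#' @param blur_fwhm_mm Full width at half maximum of the optional
#'   Gaussian blur, mm; 0 disables blurring. The scanner resolution is
#'   about 0.8 mm FWHM.
#' @param solver Passed to [generate_roi_set()].
#' @return A list of class `phantom_4d`: `volume` (4D array, MBq/mL),
#'   `rois` (list of 4 [cylindrical_roi()]), `voxel_mm`, `tacs` (the
#'   painted [tac_table()]), `cfg`.
#' @export
generate_phantom_4d <- function(cfg, dims = c(24, 24, 64), voxel_mm = 0.4,
                                blur_fwhm_mm = 0, solver = solver_control()) {
  stopifnot(inherits(cfg, "synthetic_config"), length(dims) == 3)
  d_stem <- cfg$geom$stem_diameter_mm
  if (is.null(d_stem)) d_stem <- 1.6
  l <- cfg$geom$roi_length_mm
  fov <- dims * voxel_mm
  if (d_stem > min(fov[1:2]))
    stop("stem diameter exceeds the transaxial field of view", call. = FALSE)
  if (4 * l > fov[3])
    stop("four ROIs of length ", l, " mm do not fit in the axial field of view",
         call. = FALSE)

  set <- generate_roi_set(cfg, solver = solver)
  tacs <- set$noiseless
  nfr <- nrow(tacs)

  centre <- fov[1:2] / 2
  z0 <- (fov[3] - 4 * l) / 2  # ROIs centred along the axis
  # voxel centres (1-based index i -> (i - 0.5) * voxel)
  cx <- (seq_len(dims[1]) - 0.5) * voxel_mm
  cy <- (seq_len(dims[2]) - 0.5) * voxel_mm
  cz <- (seq_len(dims[3]) - 0.5) * voxel_mm
  in_stem <- outer((cx - centre[1])^2, (cy - centre[2])^2, "+") <=
    (d_stem / 2)^2

  vol <- array(0, dim = c(dims, nfr))
  cols <- c("input", "roi1", "roi2", "roi3")
  rois <- vector("list", 4)
  for (s in 1:4) {
    zlo <- z0 + (s - 1) * l
    zsel <- cz > zlo & cz <= zlo + l
    rois[[s]] <- cylindrical_roi(
      start_mm = c(centre, zlo), end_mm = c(centre, zlo + l),
      diameter_mm = d_stem, label = cols[s]
    )
    for (f in seq_len(nfr)) {
      slab <- vol[, , zsel, f, drop = FALSE]
      slab[] <- rep(in_stem * tacs[[cols[s]]][f], sum(zsel))
      vol[, , zsel, f] <- slab
    }
  }

  if (blur_fwhm_mm > 0) {
    sigma_vox <- blur_fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
    for (f in seq_len(nfr))
      vol[, , , f] <- gaussian_blur_3d(vol[, , , f], sigma_vox)
  }

  structure(list(volume = vol, rois = rois, voxel_mm = voxel_mm,
                 tacs = tacs, cfg = cfg),
            class = "phantom_4d")
}

# Separable 3D Gaussian blur with zero-padding boundaries.
gaussian_blur_3d <- function(a, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  for (axis in 1:3) a <- convolve_axis(a, kern, axis)
  a
}

convolve_axis <- function(a, kern, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  r <- (length(kern) - 1) / 2
  pad <- matrix(0, nrow = r, ncol = ncol(m))
  mp <- rbind(pad, m, pad)
  out <- matrix(0, nrow = d[axis], ncol = ncol(m))
  for (j in seq_along(kern))
    out <- out + kern[j] * mp[j:(j + d[axis] - 1), , drop = FALSE]
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}
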