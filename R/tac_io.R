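# Reading and writing TAC tables and ROI definitions, and extraction of
# TACs from 4D volumes with cylindrical ROIs.
#
# TAC CSV dialect: header `time_min,input,roi1,roi2,roi3`, one row per
# frame, concentrations in MBq/mL. A JSON sidecar (same path + ".json")
# carries the ROI geometry and the decay-correction flag.

TAC_COLUMNS <- c("time_min", "input", "roi1", "roi2", "roi3")

#' Write a TAC table (and its geometry sidecar) to CSV
#'
#' @param tac A [tac_table()].
#' @param path Output CSV path.
#' @param geom Optional [roi_geometry()] written, together with the frame
#'   width and decay-correction flag, to a JSON sidecar at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tac, path, geom = NULL) {
  stopifnot(inherits(tac, "tac_table"))
  write.csv(as.data.frame(tac)[TAC_COLUMNS], path, row.names = FALSE)
  if (!is.null(geom)) {
    stopifnot(inherits(geom, "roi_geometry"))
    side <- list(
      roi_length_mm = geom$roi_length_mm, n_rois = geom$n_rois,
      shoot_class = geom$shoot_class, position_cm = geom$position_cm,
      stem_diameter_mm = geom$stem_diameter_mm,
      frame_width_min = attr(tac, "frame_width_min"),
      decay_corrected = attr(tac, "decay_corrected")
    )
    jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a TAC table from CSV
#'
#' Validates the declared header, strictly increasing frame times and
#' finite concentrations; errors name the offending row. When a JSON
#' sidecar written by [write_tac_table()] is present its frame width and
#' decay-correction flag are honoured.
#'
#' @param path CSV path.
#' @return A list with elements `tac` (a [tac_table()]) and `geom` (a
#'   [roi_geometry()] or `NULL` if no sidecar was found).
#' @export
read_tac_table <- function(path) {
  df <- read.csv(path)
  missing <- setdiff(TAC_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("TAC file '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  side_path <- paste0(path, ".json")
  w <- 5; dc <- TRUE; geom <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$frame_width_min)) w <- as.numeric(side$frame_width_min)
    if (!is.null(side$decay_corrected)) dc <- side$decay_corrected
    num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
    geom <- roi_geometry(
      roi_length_mm = as.numeric(side$roi_length_mm),
      shoot_class = if (is.null(side$shoot_class)) "primary" else side$shoot_class,
      position_cm = num_or_null(side$position_cm),
      stem_diameter_mm = num_or_null(side$stem_diameter_mm)
    )
  } else if (nrow(df) >= 2) {
    w <- df$time_min[2] - df$time_min[1]
  }
  tac <- tac_table(df$time_min, df$input, df$roi1, df$roi2, df$roi3,
                   frame_width_min = w, decay_corrected = dc)
  list(tac = tac, geom = geom)
}

#' Cylindrical region of interest in image coordinates
#'
#' Physical coordinates follow the voxel-centre convention: the centre of
#' voxel `(i, j, k)` (1-based) is at `(index - 0.5) * voxel_size` mm.
#'
#' @param start_mm,end_mm Axis end points, mm, length-3 numeric.
#' @param diameter_mm Cylinder diameter, mm (3 mm primary / 5 mm
#'   secondary are typical).
#' @param label Character label.
#' @return An object of class `cylindrical_roi`.
#' @export
cylindrical_roi <- function(start_mm, end_mm, diameter_mm, label = "roi") {
  stopifnot(length(start_mm) == 3, length(end_mm) == 3)
  if (diameter_mm <= 0) stop("'diameter_mm' must be positive", call. = FALSE)
  if (sqrt(sum((end_mm - start_mm)^2)) <= 0)
    stop("ROI axis must have positive length", call. = FALSE)
  structure(list(start_mm = as.numeric(start_mm),
                 end_mm = as.numeric(end_mm),
                 diameter_mm = diameter_mm, label = label),
            class = "cylindrical_roi")
}

#' Write / read cylindrical ROI definitions as YAML
#'
#' @param rois A list of [cylindrical_roi()] objects.
#' @param path YAML file path.
#' @return `write_roi_yaml()` returns `path` invisibly; `read_roi_yaml()`
#'   returns a list of [cylindrical_roi()].
#' @export
write_roi_yaml <- function(rois, path) {
  if (inherits(rois, "cylindrical_roi")) rois <- list(rois)
  payload <- lapply(rois, function(r)
    list(label = r$label, start_mm = r$start_mm, end_mm = r$end_mm,
         diameter_mm = r$diameter_mm))
  yaml::write_yaml(list(coordinate_convention = "voxel-centre, 0.5-offset",
                        rois = payload), path)
  invisible(path)
}

#' @rdname write_roi_yaml
#' @export
read_roi_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  lapply(spec$rois, function(r)
    cylindrical_roi(unlist(r$start_mm), unlist(r$end_mm), r$diameter_mm,
                    r$label))
}

#' Extract a TAC from a 4D volume with a cylindrical ROI
#'
#' Averages, per frame, the voxels whose centres fall inside the
#' cylinder (centre-inside membership, no partial-volume weighting).
#'
#' @param volume A 4D array `(x, y, z, frame)` in MBq/mL, or a
#'   `phantom_4d` object.
#' @param roi A [cylindrical_roi()].
#' @param voxel_mm Isotropic voxel size, mm (taken from the phantom when
#'   `volume` is a `phantom_4d`).
#' @return Numeric vector of per-frame means, MBq/mL.
#' @export
extract_roi_tac <- function(volume, roi, voxel_mm = NULL) {
  if (inherits(volume, "phantom_4d")) {
    if (is.null(voxel_mm)) voxel_mm <- volume$voxel_mm
    volume <- volume$volume
  }
  stopifnot(inherits(roi, "cylindrical_roi"), length(dim(volume)) == 4,
            is.numeric(voxel_mm), voxel_mm > 0)
  d <- dim(volume)
  cx <- (seq_len(d[1]) - 0.5) * voxel_mm
  cy <- (seq_len(d[2]) - 0.5) * voxel_mm
  cz <- (seq_len(d[3]) - 0.5) * voxel_mm
  grid <- expand.grid(x = cx, y = cy, z = cz)
  axis <- roi$end_mm - roi$start_mm
  len <- sqrt(sum(axis^2))
  u <- axis / len
  rel <- cbind(grid$x - roi$start_mm[1], grid$y - roi$start_mm[2],
               grid$z - roi$start_mm[3])
  proj <- rel %*% u
  radial2 <- rowSums(rel^2) - proj^2
  inside <- proj >= 0 & proj <= len & radial2 <= (roi$diameter_mm / 2)^2
  if (!any(inside))
    stop(sprintf("ROI '%s' contains no voxel centres; it is too small for this grid",
                 roi$label), call. = FALSE)
  vmat <- matrix(volume, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(matrix(vmat[inside, , drop = FALSE], ncol = d[4]))
}

#' Write a 4D phantom as a NIfTI volume plus a ROI YAML
#'
#' Requires the suggested `RNifti` package.
#'
#' @param phantom A `phantom_4d` from [generate_phantom_4d()].
#' @param nii_path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param roi_path Optional YAML path for the ROI definitions.
#' @return `nii_path`, invisibly.
#' @export
write_phantom_nifti <- function(phantom, nii_path, roi_path = NULL) {
  stopifnot(inherits(phantom, "phantom_4d"))
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI requires the 'RNifti' package", call. = FALSE)
  img <- RNifti::asNifti(phantom$volume,
                         pixdim = c(rep(phantom$voxel_mm, 3), 1))
  RNifti::writeNifti(img, nii_path)
  if (!is.null(roi_path)) write_roi_yaml(phantom$rois, roi_path)
  invisible(nii_path)
}
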