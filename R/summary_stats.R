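# Descriptive summaries of calibrated parameters across ROI sets and
# plain correlations with position along the shoot. Mixed-model
# significance testing is deliberately left to general statistics
# tooling; this module exports tidy tables for that purpose.

#' Assemble a tidy parameter table from a list of fits
#'
#' @param fits A list of `calibration_result` objects.
#' @param plant_id,shoot_class,position_cm Optional vectors (recycled)
#'   of per-fit metadata; `shoot_class` and `position_cm` default to the
#'   fit's own geometry when present.
#' @param labels Optional ROI-set labels (default `set1`, `set2`, ...).
#' @return A data.frame with one row per fit: `label`, `plant_id`,
#'   `shoot_class`, `position_cm`, fitted `s_ph`, `a12`, `a21`, `b`,
#'   `c`, `h`, `rmse`, `converged`.
#' @export
parameter_table <- function(fits, plant_id = NA, shoot_class = NULL,
                            position_cm = NULL, labels = NULL) {
  stopifnot(length(fits) >= 1)
  n <- length(fits)
  if (is.null(labels)) labels <- paste0("set", seq_len(n))
  plant_id <- rep_len(plant_id, n)
  rows <- lapply(seq_len(n), function(i) {
    f <- fits[[i]]
    stopifnot(inherits(f, "calibration_result"))
    sc <- if (!is.null(shoot_class)) rep_len(shoot_class, n)[i]
          else f$geom$shoot_class
    pos <- if (!is.null(position_cm)) rep_len(position_cm, n)[i]
           else if (!is.null(f$geom$position_cm)) f$geom$position_cm
           else NA_real_
    p <- f$params
    data.frame(label = labels[i], plant_id = plant_id[i],
               shoot_class = sc, position_cm = pos,
               s_ph = p$s_ph, a12 = p$a12, a21 = p$a21, b = p$b,
               c = p$c, h = p$h, rmse = f$rmse,
               converged = f$converged)
  })
  do.call(rbind, rows)
}

#' Group means and standard errors of a fitted parameter
#'
#' Arithmetic mean and standard error (`sd / sqrt(n)`) of one parameter
#' per group, mirroring mean +- SE reporting across ROI sets. Groups
#' with fewer than two rows get an `NA` standard error and a flag.
#'
#' @param table A data.frame such as [parameter_table()] output.
#' @param parameter Column to summarize (e.g. `"s_ph"`).
#' @param group Grouping column (e.g. `"shoot_class"`).
#' @return A data.frame with columns `group`, `n`, `mean`, `se`,
#'   `se_defined`.
#' @examples
#' df <- data.frame(g = "a", v = c(100, 120, 140, 160))
#' summarize_by_group(df, "v", "g")  # mean 130, SE 12.91
#' @export
summarize_by_group <- function(table, parameter, group) {
  stopifnot(parameter %in% names(table), group %in% names(table))
  parts <- split(table[[parameter]], table[[group]])
  rows <- lapply(names(parts), function(g) {
    v <- parts[[g]]
    n <- length(v)
    se <- if (n >= 2) sd(v) / sqrt(n) else NA_real_
    data.frame(group = g, n = n, mean = mean(v), se = se,
               se_defined = n >= 2)
  })
  out <- do.call(rbind, rows)
  if (any(!out$se_defined))
    warning("some groups have fewer than 2 rows; their SE is undefined",
            call. = FALSE)
  out
}

#' Correlation of a fitted parameter with position along the shoot
#'
#' Plain Pearson or Spearman correlation with a two-sided p-value,
#' wrapping [stats::cor.test()].
#'
#' @param table A data.frame with the parameter and a position column.
#' @param parameter Parameter column name.
#' @param method `"pearson"` or `"spearman"`.
#' @param position Position column name (default `"position_cm"`).
#' @return A list with `estimate` (r or rho), `p_value`, `method`, `n`.
#' @export
correlate_with_position <- function(table, parameter,
                                    method = c("pearson", "spearman"),
                                    position = "position_cm") {
  method <- match.arg(method)
  stopifnot(parameter %in% names(table), position %in% names(table))
  x <- table[[position]]; y <- table[[parameter]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("correlation needs at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: a column is constant", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = method,
                                  alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(x))
}
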