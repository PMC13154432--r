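#!/usr/bin/env Rscript
# Step 1: simulate a cohort of PET acquisitions.
#
# Four plants, each contributing two primary-shoot and two
# secondary-shoot ROI sets (16 sets in total), with ground-truth
# transport parameters drawn around the magnitudes observed in
# Arabidopsis inflorescences: faster phloem fronts and stronger
# unloading in primary shoots, stronger storage in secondary shoots.
# Each set gets a 5 % multiplicative-noise acquisition plus its
# noiseless counterpart and a ground-truth sidecar.

suppressPackageStartupMessages(library(phloempet))
seed <- 20260924L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

set.seed(seed)
truths <- list()
for (plant in 1:4) {
  for (k in 1:2) {
    label <- sprintf("plant%d_primary%d", plant, k)
    truths[[label]] <- list(
      params = model_parameters(rnorm(1, 128, 25), runif(1, 0.15, 0.34),
                                runif(1, 0.04, 0.12), runif(1, 0.28, 0.45)),
      geom = roi_geometry(shoot_class = "primary",
                          position_cm = runif(1, 11, 21),
                          stem_diameter_mm = runif(1, 1.5, 1.8)),
      plant_id = paste0("plant", plant))
    label <- sprintf("plant%d_secondary%d", plant, k)
    truths[[label]] <- list(
      params = model_parameters(rnorm(1, 70, 12), runif(1, 0.04, 0.12),
                                runif(1, 0.15, 0.32), runif(1, 0.2, 0.4)),
      geom = roi_geometry(shoot_class = "secondary",
                          position_cm = runif(1, 11, 21),
                          stem_diameter_mm = runif(1, 1.3, 1.6)),
      plant_id = paste0("plant", plant))
  }
}

manifest <- data.frame()
for (label in names(truths)) {
  tr <- truths[[label]]
  cfg <- synthetic_config(params = tr$params, geom = tr$geom,
                          peak_time_min = runif(1, 63, 70),
                          noise_cv = 0.05,
                          seed = derive_seed(seed, label))
  roi_set <- generate_roi_set(cfg,
                              solver = solver_control(hmax_min = 0.1,
                                                      dt_out_min = 0.5))
  path <- file.path(out_dir, paste0(label, ".csv"))
  write_tac_table(roi_set$noisy, path, geom = tr$geom)
  p <- tr$params
  jsonlite::write_json(
    list(label = label, plant_id = tr$plant_id,
         truth = list(s_ph = p$s_ph, a12 = p$a12, a21 = p$a21,
                      b = p$b, c = p$c, h = p$h),
         noise_cv = cfg$noise_cv, peak_time_min = cfg$peak_time_min),
    file.path(out_dir, paste0(label, "_truth.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- rbind(manifest,
                    data.frame(label = label, plant_id = tr$plant_id,
                               shoot_class = tr$geom$shoot_class,
                               position_cm = tr$geom$position_cm,
                               tac_file = basename(path)))
}
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
cat(sprintf("Simulated %d ROI sets (%d primary, %d secondary) into %s\n",
            nrow(manifest), sum(manifest$shoot_class == "primary"),
            sum(manifest$shoot_class == "secondary"), out_dir))
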