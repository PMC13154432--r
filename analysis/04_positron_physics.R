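#!/usr/bin/env Rscript
# Step 4: positron-annihilation geometry for thin stems.
#
# For a grid of stem diameters spanning the measured range (1.3-1.8 mm)
# and beyond, estimate the probability that a positron born in the
# phloem annihilates inside the stem, together with the mean capped
# in-stem travel distance. A probability well above 50 % for the
# measured diameters is what makes PET imaging of these shoots
# interpretable as in-stem tracer signal.

suppressPackageStartupMessages(library(phloempet))
seed <- 20260924L
dir.create("results", showWarnings = FALSE)

grid <- c(1.0, 1.3, 1.5, 1.8, 2.5, 4.0)
rows <- lapply(grid, function(d) {
  est <- annihilation_probability(stem_cylinder(d), n_samples = 1e6,
                                  seed = derive_seed(seed, sprintf("d%.1f", d)))
  data.frame(diameter_mm = d,
             p_annihilation = est$p_annihilation,
             p_direct = est$p_direct,
             mean_chord_mm = est$mean_chord_mm,
             mean_travel_mm = est$mean_travel_mm,
             se_direct = est$se_direct)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/annihilation.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\nMeasured stems (1.3-1.8 mm): P_annihilation %.0f-%.0f%%\n",
            tab$p_annihilation[tab$diameter_mm == 1.3],
            tab$p_annihilation[tab$diameter_mm == 1.8]))
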