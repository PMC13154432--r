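#!/usr/bin/env Rscript
# Step 5: descriptive summaries of the fitted transport parameters.
#
# Group means +- SE by shoot class for every parameter, and plain
# correlations of each parameter with position along the shoot
# (Pearson and Spearman) within the primary-shoot fits. Mixed-model
# hypothesis testing is deliberately out of scope here; the tidy
# parameter table is the hand-off point for that.

suppressPackageStartupMessages(library(phloempet))
fits_dir <- "results/fits"

tab <- read.csv(file.path(fits_dir, "parameter_table.csv"))
cat(sprintf("%d fits (%d primary, %d secondary)\n\n", nrow(tab),
            sum(tab$shoot_class == "primary"),
            sum(tab$shoot_class == "secondary")))

summaries <- read.csv(file.path(fits_dir, "group_summaries.csv"))
cat("Group summaries (mean +- SE by shoot class):\n")
for (p in unique(summaries$parameter)) {
  s <- summaries[summaries$parameter == p, ]
  cat(sprintf("  %-5s %s\n", p,
              paste(sprintf("%s: %.3g +- %.2g (n=%d)", s$group, s$mean,
                            s$se, s$n), collapse = "   ")))
}

prim <- tab[tab$shoot_class == "primary" & is.finite(tab$position_cm), ]
cors <- data.frame()
for (p in c("s_ph", "a12", "b", "c")) {
  for (m in c("pearson", "spearman")) {
    ct <- correlate_with_position(prim, p, m)
    cors <- rbind(cors, data.frame(parameter = p, method = m,
                                   estimate = ct$estimate,
                                   p_value = ct$p_value, n = ct$n))
  }
}
write.csv(cors, file.path(fits_dir, "position_correlations.csv"),
          row.names = FALSE)
cat("\nCorrelation with position along the primary shoot:\n")
print(cors, row.names = FALSE, digits = 3)
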