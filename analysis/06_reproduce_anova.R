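#!/usr/bin/env Rscript
# Step 6: recompute the three-group ANOVA F statistics directly from the
# published per-group means, SDs and sample sizes, and compare with the
# published F values.  Rounding of the printed cells limits agreement for
# the susceptibility table (means printed to 2 significant figures); the
# volume table reproduces to 2 decimal places for most regions.

library(qsmcohort)
dir.create("results", showWarnings = FALSE)
ref <- subcortical_reference_stats()

rows <- do.call(rbind, lapply(unique(ref$measure), function(ms) {
  do.call(rbind, lapply(unique(ref$region), function(r) {
    cell <- ref[ref$region == r & ref$measure == ms, ]
    a <- anova_from_summary(cell$mean, cell$sd, cell$n)
    data.frame(region = r, measure = ms, f_recomputed = a$F,
               p_recomputed = a$p, f_published = cell$f_published[1],
               abs_diff = abs(round(a$F, 2) - cell$f_published[1]))
  }))
}))
write.csv(rows, "results/anova_reproduction.csv", row.names = FALSE)

vol <- rows[rows$measure == "volume_mm3", ]
message("volume F statistics (recomputed vs published):")
for (i in seq_len(nrow(vol)))
  message(sprintf("  %-24s %5.2f  vs %5.2f%s", vol$region[i],
                  vol$f_recomputed[i], vol$f_published[i],
                  ifelse(vol$abs_diff[i] <= 0.02, "", "  (printed-cell rounding)")))
message("susceptibility cells are printed to ~2 significant figures; ",
        "recomputed F drifts by up to ",
        round(max(rows$abs_diff[rows$measure == "susceptibility_ppm"]), 2),
        " there (see results/anova_reproduction.csv)")
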