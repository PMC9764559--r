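#!/usr/bin/env Rscript
# Paired tumor vs juxta-tumor analytics: per-analyte log10(T/J) ratios with
# paired t tests on logged concentrations, and the secretome-based patient
# distance (Euclidean on natural-log concentrations over the full panel) cut
# into low / intermediate / high groups at its 0.15 / 0.85 quantiles.

library(secretoscope)

lod <- read_lod_table("results/cohort/lod.csv")
sec <- impute_detection_limits(
  read_secretome_table("results/cohort/secretome.csv", lod), lod)
retained <- low_detection_filter(sec)$retained

cmp <- comparison_table(sec, analyte_set = retained)
write_csv_table(cmp, "results/comparison_table.csv")
up <- cmp$median_ratio > 1 & cmp$p.value <= 0.05
down <- cmp$median_ratio < 1 & cmp$p.value <= 0.05
cat(sprintf("%d/%d analytes significantly higher in tumors (%.0f%%), %d lower\n",
            sum(up), nrow(cmp), 100 * mean(up), sum(down)))
cat("top tumor-enriched analytes:\n")
print(head(cmp[, c("analyte", "median_ratio", "p.value", "code")], 8),
      row.names = FALSE, digits = 3)

d <- secretome_distance(sec)   # all 55 analytes, low-detection ones included
dg <- distance_groups(d)
write_csv_table(as.data.frame(dg), "results/distance_groups.csv")
cat(sprintf("distance groups: %s (cuts %.2f / %.2f)\n",
            paste(names(table(dg$group)), table(dg$group),
                  sep = "=", collapse = "  "),
            attr(dg, "cut_low"), attr(dg, "cut_high")))
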