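#!/usr/bin/env Rscript
# Read the cohort tables back from disk, apply the detection-limit
# imputation rules (below-LOD cells -> half the mean lower limit of the
# analyte's out-of-range batches; above-LOD cells -> the analyte's maximum
# upper limit) and the low-detection exclusion (< 5% in-range detection in
# juxta-tumors), and persist the preprocessed matrix.

library(secretoscope)

lod <- read_lod_table("results/cohort/lod.csv")
sec <- read_secretome_table("results/cohort/secretome.csv", lod)

imp <- impute_detection_limits(sec, lod)
counts <- attr(imp, "imputed_counts")
cat(sprintf("imputed %d below-LOD and %d above-LOD cells\n",
            sum(counts$below), sum(counts$above)))

ld <- low_detection_filter(imp)
cat(sprintf("excluded for low detection (< 5%% of juxta samples): %s\n",
            paste(ld$excluded, collapse = ", ")))
cat(sprintf("%d analytes retained for multiparametric analyses\n",
            length(ld$retained)))

dir.create("results", showWarnings = FALSE)
write_secretome_table(imp, "results/secretome_imputed.csv")
write_csv_table(data.frame(analyte = names(ld$rates),
                           detection_rate = round(ld$rates, 4),
                           excluded = names(ld$rates) %in% ld$excluded),
                "results/low_detection.csv")
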