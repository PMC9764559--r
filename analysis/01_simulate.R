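#!/usr/bin/env Rscript
# Generate the default paired tumor/juxta-tumor cohort (422 patients, 55
# analytes, 4 assay batches) and write it out as the three delimited tables
# every later step starts from, plus the generator's ground truth.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(secretoscope)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

cfg <- default_cohort_config()
g <- generate_cohort(cfg, seed = substream_seed(seed, "synthetic-master"))

write_secretome_table(g$cohort$secretome, "results/cohort/secretome.csv")
write_csv_table(g$lod, "results/cohort/lod.csv")
write_csv_table(g$cohort$clinical, "results/cohort/clinical.csv")
write_csv_table(g$truth$analytes, "results/cohort/truth_analytes.csv")
write_csv_table(g$truth$patients, "results/cohort/truth_patients.csv")

sec <- g$cohort$secretome
cat(sprintf("wrote %d samples (%d patients) x %d analytes\n",
            nrow(sec$values), cfg$n_patients, ncol(sec$values)))
cat(sprintf("cells: %s\n", paste(names(table(sec$flags)), table(sec$flags),
                                 sep = "=", collapse = "  ")))
cat(sprintf("planted discriminative analytes: %s\n",
            paste(g$truth$analytes$analyte[g$truth$analytes$discriminative],
                  collapse = ", ")))
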