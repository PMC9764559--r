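#!/usr/bin/env Rscript
# Unsupervised structure of the secretome: correlation PCA of all samples
# (missing cells completed by regularized iterative PCA) with per-tissue
# 95% Gaussian ellipses, and Ward clustering of the tumor-specific log
# ratios into five metamolecules.

library(secretoscope)

lod <- read_lod_table("results/cohort/lod.csv")
sec <- impute_detection_limits(
  read_secretome_table("results/cohort/secretome.csv", lod), lod)
retained <- low_detection_filter(sec)$retained

lg <- log_transform(select_analytes(sec, retained), 10)
completed <- iterative_pca_impute(lg$values, ncp = 2)
pca <- run_pca(completed)
cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2]))
ell <- gaussian_ellipse(pca$scores[, 1:2], lg$samples$tissue)
sep <- abs(diff(vapply(split(pca$scores[, 1], lg$samples$tissue), mean, 1)))
cat(sprintf("tumor/juxta separation on PC1: %.1f score units\n", sep))
write_csv_table(data.frame(sample_id = rownames(pca$scores),
                           tissue = lg$samples$tissue, pca$scores[, 1:2]),
                "results/pca_scores.csv")
write_csv_table(data.frame(analyte = rownames(pca$contributions),
                           round(pca$contributions[, 1:2], 3)),
                "results/pca_contributions.csv")

rat <- tumor_juxta_ratios(sec)
ratios <- iterative_pca_impute(rat$values[, retained], ncp = 2)
cl <- cluster_ratio_analytes(ratios, k = 5)
mm <- metamolecule_values(ratios, cl$assignment)
cat("metamolecule summary (clusters ordered by descending median fold):\n")
print(mm$summary, digits = 3, row.names = FALSE)
write_csv_table(data.frame(analyte = names(cl$assignment),
                           cluster = unname(cl$assignment)),
                "results/metamolecule_clusters.csv")
write_csv_table(mm$summary, "results/metamolecule_summary.csv")
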