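#!/usr/bin/env Rscript
# The tumorness signature: 70/30 patient split, filters, 30 chained-equation
# imputations per side, per-imputation elastic nets with CV lambda, alpha
# chosen across imputations, strict-majority stability aggregation, ROC-
# corner cutoff, evaluation on train and test, ANOVA association with
# clinical features. This is the expensive step (several minutes).
#
# Usage: Rscript analysis/05_signature.R [seed]

library(secretoscope)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1

lod <- read_lod_table("results/cohort/lod.csv")
cohort <- paired_cohort(
  read_secretome_table("results/cohort/secretome.csv", lod),
  read_clinical_table("results/cohort/clinical.csv"))

fit <- fit_tumor_signature(cohort, lod, seed = substream_seed(seed, "signature"))
print(fit)
cat(sprintf("alpha = %.1f; %d analytes in the signature:\n",
            fit$alpha, length(fit$model$analytes)))
print(round(sort(fit$model$coef_std, decreasing = TRUE), 3))

jsonlite::write_json(
  fit$model[c("analytes", "coef_raw", "coef_std", "intercept_raw",
              "intercept_std", "score_cutoff", "prob_cutoff", "alpha", "m")],
  "results/signature_model.json", auto_unbox = TRUE, digits = NA)
write_csv_table(data.frame(
  set = c("train", "test"),
  accuracy = c(fit$eval_train$accuracy, fit$eval_test$accuracy),
  sensitivity = c(fit$eval_train$sensitivity, fit$eval_test$sensitivity),
  specificity = c(fit$eval_train$specificity, fit$eval_test$specificity),
  auc = c(fit$eval_train$auc, fit$eval_test$auc)),
  "results/signature_performance.csv")
write_csv_table(fit$eval_test$roc, "results/roc_test.csv")
write_csv_table(fit$clinical_assoc, "results/clinical_association.csv")

cat("clinical features associated with the tumor signature:\n")
print(fit$clinical_assoc[order(fit$clinical_assoc$p.value), ],
      row.names = FALSE, digits = 3)
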