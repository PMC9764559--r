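#' Fit the tumorness signature end to end
#'
#' Runs the whole supervised procedure on a paired cohort: LOD imputation and
#' low-detection exclusion, log10 transform, patient-level 70/30 split,
#' near-zero-variance filter (train side), chained-equations multiple
#' imputation run separately on train and test (clinical covariates and the
#' tissue outcome forced into the imputation models), removal of highly
#' correlated analytes on the train side, per-imputation elastic nets with
#' CV-selected lambda and an alpha chosen across imputations, stability
#' aggregation (strict majority + median pooling), ROC-corner cutoff on the
#' train scores, and evaluation on train (control) and test. Test-set sample
#' scores are pooled by averaging over the test-side imputations before
#' thresholding. One master seed fixes split, imputation streams and CV
#' folds, so the whole fit is reproducible bit for bit.
#'
#' @param cohort a [paired_cohort()] (linear scale, censor flags set).
#' @param lod a [lod_table()].
#' @param seed master seed.
#' @param fraction train fraction, default 0.7.
#' @param m imputations, default 30.
#' @param maxit chained-equation cycles, default 10.
#' @param nfolds CV folds, default 10.
#' @param alpha_grid alpha grid, default `seq(0.1, 1, 0.1)`.
#' @param cor_cutoff correlation-filter threshold, default 0.8.
#' @param detection_threshold low-detection exclusion threshold, default 0.05.
#' @param forced_clinical clinical columns forced into the imputation model.
#' @return object of class `tumor_signature_fit`: list with `model`
#'   (the [aggregate_signature()] result with cutoffs set), `alpha`,
#'   `alpha_metrics`, `split`, `predictors` (post-filter analytes),
#'   `excluded_low_detection`, `eval_train`, `eval_test`,
#'   `clinical_assoc`, and the settings used.
#' @export
fit_tumor_signature <- function(cohort, lod, seed = 1, fraction = 0.7,
                                m = 30, maxit = 10, nfolds = 10,
                                alpha_grid = seq(0.1, 1, 0.1),
                                cor_cutoff = 0.8, detection_threshold = 0.05,
                                forced_clinical = c("surgery_type",
                                                    "age_at_diagnosis",
                                                    "molecular_class",
                                                    "n_invaded_nodes",
                                                    "vascular_emboli")) {
  stopifnot(inherits(cohort, "paired_cohort"))
  sec <- impute_detection_limits(cohort$secretome, lod)
  ld <- low_detection_filter(sec, detection_threshold)
  lg <- log_transform(select_analytes(sec, ld$retained), 10)

  samples <- lg$samples
  split <- split_train_test(unique(samples$patient_id), fraction,
                            substream_seed(seed, "split"))
  side <- function(pats) {
    rows <- samples$patient_id %in% pats
    list(x = lg$values[rows, , drop = FALSE],
         y = samples$tissue[rows],
         patient_id = samples$patient_id[rows])
  }
  tr <- side(split$train); te <- side(split$test)

  # variable filters are decided on the train side only
  nzv_keep <- near_zero_variance_filter(tr$x)
  tr$x <- tr$x[, nzv_keep, drop = FALSE]
  te$x <- te$x[, nzv_keep, drop = FALSE]

  impute_side <- function(s, stream) {
    cl <- cohort$clinical[match(s$patient_id, cohort$clinical$patient_id), ]
    forced_ok <- intersect(forced_clinical, names(cl))
    df <- cbind(as.data.frame(s$x), cl[forced_ok], tissue = s$y)
    multiple_impute(df, forced = c(forced_ok, "tissue"), m = m, maxit = maxit,
                    seed = substream_seed(seed, stream))
  }
  mi_tr <- impute_side(tr, "mi-train")
  mi_te <- impute_side(te, "mi-test")
  xmats <- function(mi, cols) lapply(mi$completions, function(d)
    as.matrix(d[cols]))

  # correlation filter on the average train correlation matrix
  cors <- Reduce(`+`, lapply(xmats(mi_tr, nzv_keep), stats::cor)) / m
  predictors <- correlation_filter(cors, cutoff = cor_cutoff, is_cor = TRUE)

  foldid <- make_pair_folds(tr$patient_id, nfolds, substream_seed(seed, "cv"))
  sel <- select_alpha(xmats(mi_tr, predictors), tr$y, grid = alpha_grid,
                      foldid = foldid)
  model <- aggregate_signature(sel$models)

  pooled_scores <- function(mi, cols) {
    sc <- vapply(xmats(mi, cols), function(xm) signature_score(model, xm),
                 numeric(length(mi$completions[[1]][[1]])))
    rowMeans(matrix(sc, ncol = length(mi$completions)))
  }
  train_scores <- pooled_scores(mi_tr, predictors)
  cut <- choose_cutoff(train_scores, tr$y)
  model$score_cutoff <- cut$score_cutoff
  model$prob_cutoff <- cut$prob_cutoff

  eval_train <- evaluate_classifier(model, labels = tr$y, scores = train_scores)
  test_scores <- pooled_scores(mi_te, predictors)
  eval_test <- evaluate_classifier(model, labels = te$y, scores = test_scores)

  tumor_scores <- c(
    stats::setNames(train_scores[tr$y == "T"], tr$patient_id[tr$y == "T"]),
    stats::setNames(test_scores[te$y == "T"], te$patient_id[te$y == "T"]))
  assoc_features <- c("pregnancy", "menopause", "ee_grade", "ki67_class",
                      "molecular_class", "vascular_emboli", "pN",
                      "lesional_code", "surgery_type")
  assoc_features <- intersect(assoc_features, names(cohort$clinical))
  clinical_assoc <- suppressWarnings(
    clinical_association(tumor_scores, cohort$clinical, assoc_features))

  structure(list(
    model = model, alpha = sel$alpha, alpha_metrics = sel$metrics,
    split = split, predictors = predictors,
    excluded_low_detection = ld$excluded,
    eval_train = eval_train, eval_test = eval_test,
    clinical_assoc = clinical_assoc,
    settings = list(seed = seed, fraction = fraction, m = m, maxit = maxit,
                    nfolds = nfolds, alpha_grid = alpha_grid,
                    cor_cutoff = cor_cutoff,
                    detection_threshold = detection_threshold)),
    class = "tumor_signature_fit")
}

#' @export
print.tumor_signature_fit <- function(x, ...) {
  cat(sprintf("<tumor_signature_fit> alpha = %.2f, %d/%d analytes retained\n",
              x$alpha, length(x$model$analytes), length(x$predictors)))
  cat(sprintf("  train: acc %.3f sens %.3f spec %.3f auc %.3f\n",
              x$eval_train$accuracy, x$eval_train$sensitivity,
              x$eval_train$specificity, x$eval_train$auc))
  cat(sprintf("  test:  acc %.3f sens %.3f spec %.3f auc %.3f\n",
              x$eval_test$accuracy, x$eval_test$sensitivity,
              x$eval_test$specificity, x$eval_test$auc))
  invisible(x)
}
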