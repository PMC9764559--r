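# The tumorness signature: paired train/test split, variable filters,
# per-imputation elastic-net fits with CV-selected lambda, stability
# aggregation across imputations, ROC-corner cutoff, evaluation and clinical
# association.

#' Patient-level train/test split
#'
#' Patients are sampled without replacement so both tissues of a patient end
#' up on the same side. `n_test = floor((1 - fraction) * n)`; with 422
#' patients and the default 0.7 fraction this gives 296 train / 126 test.
#'
#' @param patients character vector of unique patient ids.
#' @param fraction train fraction in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `test` patient id vectors.
#' @export
split_train_test <- function(patients, fraction = 0.7, seed = 1) {
  patients <- unique(patients)
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  set.seed(seed)
  n_test <- floor((1 - fraction) * length(patients))
  test <- sample(patients, n_test)
  list(train = setdiff(patients, test), test = test)
}

#' Near-zero-variance variable filter
#'
#' Drops variables whose most-frequent / second-most-frequent value ratio
#' exceeds `freq_cut` while the fraction of distinct values is below
#' `unique_cut` percent; constant variables are always dropped. The rule is
#' evaluated by [caret::nearZeroVar()].
#'
#' @param x data.frame or matrix of variables (columns).
#' @param freq_cut frequency-ratio threshold, default 19 (i.e. 95/5).
#' @param unique_cut percent-unique threshold, default 10.
#' @return character vector of retained column names.
#' @export
near_zero_variance_filter <- function(x, freq_cut = 19, unique_cut = 10) {
  x <- as.data.frame(x)
  drop <- caret::nearZeroVar(x, freqCut = freq_cut, uniqueCut = unique_cut)
  retained <- if (length(drop)) names(x)[-drop] else names(x)
  if (!length(retained)) abort("all variables are near-zero-variance")
  retained
}

#' Greedy removal of highly correlated variables
#'
#' While any absolute pairwise correlation exceeds `cutoff`, take the
#' worst-offending pair and remove the member with the larger mean absolute
#' correlation against all remaining variables (ties broken by removing the
#' lexicographically later name). Deterministic.
#'
#' @param x numeric matrix/data.frame (complete), or a correlation matrix
#'   when `is_cor = TRUE`.
#' @param cutoff absolute-correlation threshold, default 0.8.
#' @param is_cor interpret `x` as a precomputed correlation matrix (used to
#'   filter on the average correlation across imputations).
#' @return character vector of retained column names.
#' @export
correlation_filter <- function(x, cutoff = 0.8, is_cor = FALSE) {
  cm <- if (is_cor) as.matrix(x) else stats::cor(as.matrix(x))
  cm <- abs(cm)
  if (is.null(colnames(cm))) colnames(cm) <- rownames(cm) <- paste0("V", seq_len(ncol(cm)))
  diag(cm) <- 0
  repeat {
    mx <- max(cm)
    if (mx <= cutoff || ncol(cm) < 2) break
    hits <- which(cm == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pair_names <- cbind(rownames(cm)[hits[, 1]], colnames(cm)[hits[, 2]])
    ord <- order(pair_names[, 1], pair_names[, 2])
    i <- hits[ord[1], 1]; j <- hits[ord[1], 2]
    mean_i <- mean(cm[i, -i]); mean_j <- mean(cm[j, -j])
    drop <- if (mean_i > mean_j) i
            else if (mean_j > mean_i) j
            else if (colnames(cm)[i] > colnames(cm)[j]) i else j
    cm <- cm[-drop, -drop, drop = FALSE]
  }
  colnames(cm)
}

# fold ids keeping both tissues of a patient in the same fold (and therefore
# tissue-balanced folds, since every patient contributes one T and one J)
make_pair_folds <- function(patient_ids, nfolds = 10, seed = 1) {
  set.seed(seed)
  patients <- sample(unique(patient_ids))
  fold_of <- stats::setNames(rep_len(seq_len(nfolds), length(patients)), patients)
  unname(fold_of[patient_ids])
}

#' Elastic-net logistic fit with 10-fold cross-validated lambda
#'
#' Predictors are standardized to unit variance internally and coefficients
#' are reported on both the standardized and the raw (log10-concentration)
#' scale. Lambda is chosen by cross-validated binomial deviance; CV folds
#' keep paired tissues together. The default rule is `lambda.1se` (the
#' largest lambda within one standard error of the CV optimum): under a
#' no-signal null the CV curve is flat and `lambda.min` degenerates to a
#' tiny penalty that keeps nearly every variable, whereas the one-SE rule
#' collapses to the empty model — the behavior a stability-selected
#' signature requires. CV AUC (rank-based) and CV accuracy are computed
#' from the prevalidated predictions at the selected lambda.
#'
#' @param x numeric predictor matrix (samples x analytes, log10 scale).
#' @param y tissue labels (`"T"`/`"J"` character or factor); `"T"` is the
#'   positive class.
#' @param alpha elastic-net mixing parameter in (0, 1].
#' @param foldid optional fold assignment (from pair-aware fold building);
#'   generated from `seed` and `patient_ids` when omitted.
#' @param patient_ids per-sample patient ids (needed when `foldid` missing).
#' @param nfolds number of CV folds, default 10.
#' @param seed seed for fold construction.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @return object of class `per_imputation_model`: list with `alpha`,
#'   `lambda`, `coef_std`, `coef_raw`, `intercept_std`, `intercept_raw`,
#'   `cv_auc`, `cv_accuracy`, `n_selected`, `center`, `scale`.
#' @export
fit_elastic_net_cv <- function(x, y, alpha, foldid = NULL, patient_ids = NULL,
                               nfolds = 10, seed = 1,
                               lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  ybin <- as.integer(as.character(y) == "T")
  if (length(unique(ybin)) < 2) abort("y must contain both classes")
  if (is.null(foldid)) {
    if (is.null(patient_ids)) abort("provide foldid or patient_ids")
    foldid <- make_pair_folds(patient_ids, nfolds, seed)
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) abort("constant predictor column: %s",
                           colnames(x)[which(scl == 0)[1]])
  xs <- scale(x, center = ctr, scale = scl)
  cv <- glmnet::cv.glmnet(xs, ybin, family = "binomial", alpha = alpha,
                          foldid = foldid, type.measure = "deviance",
                          standardize = FALSE, keep = TRUE)
  lam <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  ilam <- which(cv$lambda == lam)[1]
  cf <- as.matrix(stats::coef(cv, s = lam))
  intercept_std <- cf[1, 1]
  coef_std <- cf[-1, 1]
  coef_raw <- coef_std / scl
  intercept_raw <- intercept_std - sum(coef_std * ctr / scl)
  preval <- cv$fit.preval[, ilam]           # link scale
  structure(list(
    alpha = alpha, lambda = lam,
    coef_std = coef_std, coef_raw = coef_raw,
    intercept_std = intercept_std, intercept_raw = intercept_raw,
    cv_auc = auc_rank(preval, ybin),
    cv_accuracy = mean((preval > 0) == ybin),
    n_selected = sum(coef_std != 0),
    center = ctr, scale = scl), class = "per_imputation_model")
}

#' Select the elastic-net alpha across imputations
#'
#' For each alpha in the grid, fits the CV elastic net on every completed
#' training table and averages CV AUC, CV accuracy and the retained-variable
#' count. The chosen alpha maximizes mean AUC; near-ties (difference below
#' `auc_tol`) are broken by higher mean accuracy — itself a noisy CV
#' estimate, so accuracy near-ties (same tolerance) fall through to the
#' deterministic criteria: fewer retained variables, then the larger
#' (sparser) alpha.
#'
#' @param x_list list of completed predictor matrices (one per imputation).
#' @param y tissue labels shared by all completions.
#' @param grid alpha grid in (0, 1], default `seq(0.1, 1, 0.1)`.
#' @param foldid CV fold assignment (shared across alphas and imputations).
#' @param auc_tol near-tie tolerance on AUC, default 0.005.
#' @return list with `alpha` (chosen), `metrics` (per-alpha summary
#'   data.frame) and `models` (the per-imputation models at the chosen
#'   alpha, reused by [aggregate_signature()]).
#' @export
select_alpha <- function(x_list, y, grid = seq(0.1, 1, 0.1), foldid,
                         auc_tol = 0.005) {
  if (!length(grid)) abort("empty alpha grid")
  if (any(grid <= 0 | grid > 1)) abort("alpha grid must lie in (0, 1]")
  fits <- lapply(grid, function(a)
    lapply(x_list, fit_elastic_net_cv, y = y, alpha = a, foldid = foldid))
  metrics <- do.call(rbind, lapply(seq_along(grid), function(k) {
    ms <- fits[[k]]
    data.frame(alpha = grid[k],
               auc = mean(vapply(ms, `[[`, numeric(1), "cv_auc")),
               accuracy = mean(vapply(ms, `[[`, numeric(1), "cv_accuracy")),
               n_selected = mean(vapply(ms, `[[`, numeric(1), "n_selected")))
  }))
  cand <- which(metrics$auc >= max(metrics$auc) - auc_tol)
  cand <- cand[metrics$accuracy[cand] >= max(metrics$accuracy[cand]) - auc_tol]
  cand <- cand[order(metrics$n_selected[cand], -metrics$alpha[cand])]
  best <- cand[1]
  list(alpha = grid[best], metrics = metrics, models = fits[[best]])
}

#' Aggregate per-imputation models into the final signature
#'
#' Retains the analytes selected (nonzero coefficient) in strictly more than
#' half of the per-imputation models; the pooled coefficient of a retained
#' analyte is the median over the models that selected it, and the pooled
#' intercept the median over all models. Coefficients are pooled on both
#' scales; the raw-scale pair defines the signature score
#' `score(x) = intercept + sum(coef * log10 value)`.
#'
#' @param models list of [fit_elastic_net_cv()] results.
#' @return object of class `signature_model`: list with `analytes`,
#'   `coef_raw`, `coef_std`, `intercept_raw`, `intercept_std`,
#'   `selection_counts`, `m`, `alpha`; score/probability cutoffs are filled
#'   in by [choose_cutoff()] via [fit_tumor_signature()].
#' @export
aggregate_signature <- function(models) {
  if (!length(models)) abort("no models to aggregate")
  m <- length(models)
  analyte_names <- names(models[[1]]$coef_std)
  selmat <- vapply(models, function(mod) mod$coef_std[analyte_names] != 0,
                   logical(length(analyte_names)))
  selmat <- matrix(selmat, length(analyte_names), m,
                   dimnames = list(analyte_names, NULL))
  counts <- rowSums(selmat)
  retained <- analyte_names[counts > m / 2]
  if (!length(retained))
    abort("no analyte was selected in more than half of the models; consider a weaker penalty (smaller alpha or larger cohort)")
  pool <- function(field, a) stats::median(
    vapply(models[selmat[a, ]], function(mod) mod[[field]][[a]], numeric(1)))
  structure(list(
    analytes = retained,
    coef_raw = stats::setNames(vapply(retained, function(a) pool("coef_raw", a), numeric(1)), retained),
    coef_std = stats::setNames(vapply(retained, function(a) pool("coef_std", a), numeric(1)), retained),
    intercept_raw = stats::median(vapply(models, `[[`, numeric(1), "intercept_raw")),
    intercept_std = stats::median(vapply(models, `[[`, numeric(1), "intercept_std")),
    selection_counts = counts, m = m, alpha = models[[1]]$alpha,
    score_cutoff = NA_real_, prob_cutoff = NA_real_),
    class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d analytes (selected in > %d/%d models), alpha = %.2f\n",
              length(x$analytes), floor(x$m / 2), x$m, x$alpha))
  cat(sprintf("  score cutoff %.3f (probability %.3f)\n", x$score_cutoff, x$prob_cutoff))
  print(round(sort(x$coef_std, decreasing = TRUE), 3))
  invisible(x)
}

#' Signature score of samples
#'
#' `score = intercept + sum(coef * log10 concentration)` over the retained
#' analytes; the predicted tumor probability is the logistic of the score.
#'
#' @param model a [aggregate_signature()] result.
#' @param x numeric matrix of log10 concentrations containing every retained
#'   analyte column.
#' @return numeric vector of scores.
#' @export
signature_score <- function(model, x) {
  x <- as.matrix(x)
  absent <- setdiff(model$analytes, colnames(x))
  if (length(absent)) abort("data lacks retained analyte(s): %s",
                            paste(absent, collapse = ", "))
  drop(model$intercept_raw + x[, model$analytes, drop = FALSE] %*% model$coef_raw)
}

#' ROC-corner classification cutoff
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores; the chosen cutoff minimizes the Euclidean distance between the
#' ROC point (FPR, TPR) and the perfect corner (0, 1), with ties broken
#' toward higher specificity. Samples with score >= cutoff are classified
#' tumor.
#'
#' @param scores numeric signature scores.
#' @param labels tissue labels (`"T"` positive / `"J"`).
#' @return list with `score_cutoff`, `prob_cutoff` (logistic of the score
#'   cutoff), `sensitivity`, `specificity` at the cutoff.
#' @export
choose_cutoff <- function(scores, labels) {
  ybin <- as.character(labels) == "T"
  if (!any(ybin) || !any(!ybin)) abort("both classes must be present")
  s <- sort(unique(scores))
  if (length(s) < 2) abort("degenerate input: all scores identical")
  cand <- (s[-1] + s[-length(s)]) / 2
  stats_at <- function(cut) {
    pred <- scores >= cut
    tpr <- sum(pred & ybin) / sum(ybin)
    fpr <- sum(pred & !ybin) / sum(!ybin)
    c(tpr = tpr, fpr = fpr, d2 = fpr^2 + (1 - tpr)^2)
  }
  st <- t(vapply(cand, stats_at, numeric(3)))
  ord <- order(st[, "d2"], st[, "fpr"], -st[, "tpr"], cand)
  best <- ord[1]
  list(score_cutoff = cand[best], prob_cutoff = stats::plogis(cand[best]),
       sensitivity = unname(st[best, "tpr"]),
       specificity = unname(1 - st[best, "fpr"]))
}

# rank-based (Mann-Whitney) AUC, used for the prevalidated CV predictions
auc_rank <- function(scores, ybin) {
  n1 <- sum(ybin); n0 <- sum(!ybin)
  (sum(rank(scores)[ybin == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC points (FPR, TPR) over decreasing score thresholds, and trapezoidal AUC
roc_curve <- function(scores, labels) {
  ybin <- as.character(labels) == "T"
  ord <- order(scores, decreasing = TRUE)
  yb <- ybin[ord]; sc <- scores[ord]
  tp <- cumsum(yb); fp <- cumsum(!yb)
  last <- !duplicated(sc, fromLast = TRUE)   # one point per distinct score
  tpr <- c(0, tp[last] / sum(ybin)); fpr <- c(0, fp[last] / sum(!ybin))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a signature classifier on labeled data
#'
#' Computes scores, logistic probabilities, hard labels by the model cutoff,
#' the confusion matrix, accuracy / sensitivity / specificity (tumor is the
#' positive class), the ROC curve and its trapezoidal AUC.
#'
#' @param model a `signature_model` with cutoffs set (or supply `cutoff`).
#' @param x log10 concentration matrix containing the retained analytes, or
#'   `NULL` when `scores` are supplied directly.
#' @param labels tissue labels aligned with rows of `x` (or `scores`).
#' @param scores optional precomputed scores (e.g. pooled over imputations).
#' @param cutoff optional score cutoff overriding the model's.
#' @return object of class `classifier_evaluation`: list with `confusion`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, `roc` (data.frame of
#'   points), `scores`, `probabilities`, `predicted`.
#' @export
evaluate_classifier <- function(model, x = NULL, labels, scores = NULL,
                                cutoff = NULL) {
  if (is.null(scores)) scores <- signature_score(model, x)
  cutoff <- cutoff %||% model$score_cutoff
  if (is.na(cutoff)) abort("model has no cutoff; run choose_cutoff first")
  ybin <- as.character(labels) == "T"
  pred <- scores >= cutoff
  confusion <- table(truth = factor(ifelse(ybin, "T", "J"), c("T", "J")),
                     predicted = factor(ifelse(pred, "T", "J"), c("T", "J")))
  tp <- confusion["T", "T"]; tn <- confusion["J", "J"]
  fn <- confusion["T", "J"]; fp <- confusion["J", "T"]
  roc <- roc_curve(scores, labels)
  structure(list(
    confusion = confusion,
    accuracy = (tp + tn) / length(ybin),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    auc = roc$auc, roc = roc$points,
    scores = scores, probabilities = stats::plogis(scores),
    predicted = ifelse(pred, "T", "J")),
    class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  print(x$confusion)
  invisible(x)
}

#' One-way ANOVA association of clinical features with the signature
#'
#' For each categorical clinical feature, a one-way ANOVA of the tumor-sample
#' signature scores across feature levels. Features with fewer than two
#' levels having at least two samples are skipped with a warning. Codes:
#' `.` <= 0.1, `*` <= 0.05, `**` <= 0.01, `***` <= 0.001.
#'
#' @param scores named numeric vector of tumor-sample signature scores
#'   (names = patient ids).
#' @param clinical clinical data.frame with `patient_id`.
#' @param features character vector of clinical column names to test.
#' @return data.frame per feature: `feature`, `F`, `p.value`, `code`, `n`.
#' @export
clinical_association <- function(scores, clinical, features) {
  rows <- lapply(features, function(f) {
    g <- clinical[[f]][match(names(scores), clinical$patient_id)]
    keep <- !is.na(g) & !is.na(scores)
    y <- scores[keep]; g <- factor(g[keep])
    ok_levels <- names(which(table(g) >= 2))
    if (length(ok_levels) < 2) {
      warning(sprintf("feature %s skipped: fewer than two usable levels", f))
      return(NULL)
    }
    keep2 <- g %in% ok_levels
    fit <- stats::aov(y[keep2] ~ droplevels(g[keep2]))
    s <- summary(fit)[[1]]
    data.frame(feature = f, F = s$`F value`[1], p.value = s$`Pr(>F)`[1],
               code = significance_code(s$`Pr(>F)`[1], dot = TRUE),
               n = sum(keep2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
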