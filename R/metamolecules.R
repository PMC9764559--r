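# Hierarchical clustering of tumor-specific log-ratios into "metamolecules":
# per-patient summaries (mean of the cluster's log10 ratios) of groups of
# analytes with a shared tumor/juxta secretion behavior.

#' Cluster analytes by their tumor-specific ratio profiles
#'
#' Agglomerative clustering of analytes (observations are the per-analyte
#' log10-ratio profiles across patients) with Euclidean distance and Ward's
#' method (`hclust` method `"ward.D2"`, the Ward criterion on Euclidean
#' distances). The dendrogram is cut into `k` clusters and labels are
#' reassigned in order of descending median metamolecule value, so cluster I
#' is always the most tumor-enriched regardless of dendrogram layout.
#'
#' @param ratios a [tumor_juxta_ratios()] result (or patients x analytes
#'   matrix) with complete cells — impute first (e.g.
#'   [iterative_pca_impute()]) if needed. Low-detection analytes should be
#'   excluded beforehand.
#' @param k number of clusters (default 5).
#' @return list with `assignment` (named character vector analyte -> label
#'   I, II, ...), `hclust` (the tree) and `k`.
#' @export
cluster_ratio_analytes <- function(ratios, k = 5) {
  vals <- if (inherits(ratios, "ratio_matrix")) ratios$values else as.matrix(ratios)
  if (anyNA(vals)) abort("ratio matrix has missing cells; impute before clustering")
  if (k > ncol(vals)) abort("k = %d exceeds the number of analytes (%d)", k, ncol(vals))
  hc <- stats::hclust(stats::dist(t(vals), method = "euclidean"), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  med <- vapply(seq_len(k), function(cl)
    stats::median(rowMeans(vals[, raw == cl, drop = FALSE])), numeric(1))
  relabel <- roman_labels(k)[rank(-med, ties.method = "first")]
  assignment <- stats::setNames(relabel[raw], names(raw))
  list(assignment = assignment, hclust = hc, k = k)
}

#' Metamolecule values and cluster summaries
#'
#' The metamolecule value of cluster X for a patient is the mean of the
#' patient's log10 ratios over the analytes of X (missing cells dropped from
#' the mean; a patient with no observed analyte in a cluster gets `NA`).
#' Cluster summaries report the median and quartiles of the patient values.
#'
#' @param ratios a [tumor_juxta_ratios()] result or patients x analytes
#'   matrix of log10 ratios (missing cells allowed).
#' @param assignment named vector analyte -> cluster label covering every
#'   analyte column of `ratios`.
#' @return object of class `metamolecule_set`: list with `values` (patients x
#'   clusters matrix of metamolecule log10 values) and `summary` (data.frame
#'   per cluster: `n_analytes`, `median`, `q1`, `q3` on the log10 scale and
#'   `median_fold` back-transformed).
#' @export
metamolecule_values <- function(ratios, assignment) {
  vals <- if (inherits(ratios, "ratio_matrix")) ratios$values else as.matrix(ratios)
  uncovered <- setdiff(colnames(vals), names(assignment))
  if (length(uncovered))
    abort("assignment does not cover analyte(s): %s", paste(uncovered, collapse = ", "))
  assignment <- assignment[colnames(vals)]
  labels <- unique(assignment)
  labels <- if (all(labels %in% roman_labels(50))) {
    labels[order(match(labels, roman_labels(50)))]
  } else sort(labels)
  mm <- vapply(labels, function(cl)
    rowMeans(vals[, assignment == cl, drop = FALSE], na.rm = TRUE), numeric(nrow(vals)))
  mm[is.nan(mm)] <- NA_real_
  mm <- matrix(mm, nrow(vals), length(labels),
               dimnames = list(rownames(vals), labels))
  qs <- t(apply(mm, 2, stats::quantile, probs = c(0.25, 0.5, 0.75), na.rm = TRUE))
  summary <- data.frame(
    cluster = labels,
    n_analytes = as.integer(table(assignment)[labels]),
    median = qs[, 2], q1 = qs[, 1], q3 = qs[, 3],
    median_fold = 10^qs[, 2],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(values = mm, summary = summary), class = "metamolecule_set")
}

#' @export
print.metamolecule_set <- function(x, ...) {
  cat(sprintf("<metamolecule_set> %d clusters x %d patients\n",
              ncol(x$values), nrow(x$values)))
  print(x$summary, digits = 3)
  invisible(x)
}
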