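# Tumor/juxta-tumor ratio analytics, univariate paired tests, the
# multivariate secretome-based distance and its quantile grouping.

#' Per-patient tumor/juxta log10 concentration ratios
#'
#' The "tumor-specific" value of an analyte for a patient is
#' log10(T) - log10(J). A cell exists iff both tissues have a non-missing
#' (possibly LOD-imputed) value; cells where either side was LOD-imputed are
#' flagged so analyses can be rerun excluding them.
#'
#' @param cohort a [paired_cohort()] or [secretome_matrix()] on the linear
#'   scale with LOD imputation already applied.
#' @return object of class `ratio_matrix`: list with `values` (patients x
#'   analytes log10 ratios) and `imputed` (logical matrix, TRUE where either
#'   side was a censoring-imputed value).
#' @export
tumor_juxta_ratios <- function(cohort) {
  m <- if (inherits(cohort, "paired_cohort")) cohort$secretome else cohort
  stopifnot(inherits(m, "secretome_matrix"))
  if (m$scale != "linear") abort("ratios are computed from the linear-scale matrix")
  ts <- tissue_split(m)
  if (any(!is.na(ts$T) & ts$T <= 0) || any(!is.na(ts$J) & ts$J <= 0))
    abort("non-positive concentrations: apply LOD imputation first")
  vals <- log10(ts$T) - log10(ts$J)
  imputed <- (ts$flags_T %in% c("below_lod", "above_lod")) |
    (ts$flags_J %in% c("below_lod", "above_lod"))
  imputed <- matrix(imputed, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  imputed[is.na(vals)] <- NA
  structure(list(values = vals, imputed = imputed), class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("<ratio_matrix> %d patients x %d analytes; %d missing cells, %d LOD-imputed\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              sum(x$imputed, na.rm = TRUE)))
  invisible(x)
}

#' Paired two-sided Student's t test with significance code
#'
#' Applied to logged concentrations of the two tissues of the same patients.
#' Incomplete pairs are dropped. A zero-variance difference vector yields a
#' degenerate result (`p = NA`, `degenerate = TRUE`) rather than a spurious
#' p-value.
#'
#' @param x,y paired numeric vectors (same length).
#' @param paired logical; `FALSE` gives the unpaired Welch test used for
#'   between-group comparisons.
#' @return list with `statistic`, `p.value`, `code`, `n`, `degenerate`.
#' @export
paired_t_test <- function(x, y, paired = TRUE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("fewer than 3 complete pairs")
  if (paired && stats::sd(x - y) == 0) {
    if (all(x == y))
      return(list(statistic = 0, p.value = 1, code = "NS", n = length(x),
                  degenerate = FALSE))
    return(list(statistic = NA_real_, p.value = NA_real_, code = NA_character_,
                n = length(x), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = paired)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       code = significance_code(tt$p.value), n = length(x), degenerate = FALSE)
}

#' Per-analyte comparison table of paired tumor vs juxta secretion
#'
#' For every analyte: the median tumor/juxta fold (back-transformed from the
#' median log10 ratio), the paired t statistic and p-value on log10
#' concentrations, and the star code.
#'
#' @param cohort a linear-scale, LOD-imputed [paired_cohort()] or
#'   [secretome_matrix()].
#' @param analyte_set optional subset of analytes.
#' @return data.frame (one row per analyte) ordered by descending median fold.
#' @export
comparison_table <- function(cohort, analyte_set = NULL) {
  m <- if (inherits(cohort, "paired_cohort")) cohort$secretome else cohort
  if (!is.null(analyte_set)) m <- select_analytes(m, analyte_set)
  rat <- tumor_juxta_ratios(m)
  lg <- log_transform(m, 10)
  ts <- tissue_split(lg)
  rows <- lapply(analytes(m), function(a) {
    tst <- paired_t_test(ts$T[, a], ts$J[, a])
    data.frame(analyte = a,
               median_ratio = 10^stats::median(rat$values[, a], na.rm = TRUE),
               statistic = tst$statistic, p.value = tst$p.value,
               code = tst$code, n = tst$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$median_ratio), ]
}

#' Contingency-table test (chi-squared with Yates correction or Fisher exact)
#'
#' For a 2x2 table: Fisher's exact test when any expected count is below 5,
#' otherwise the chi-squared test with Yates continuity correction. Larger
#' 2xK tables use the plain chi-squared test unless expected counts are low,
#' in which case Fisher's exact test is used.
#'
#' @param tab matrix of non-negative integer counts.
#' @param method `"auto"` applies the expected-count rule; `"fisher"` and
#'   `"chisq"` force the respective test.
#' @param expected_min expected-count threshold switching to the exact test.
#' @return list with `p.value` and `method`.
#' @export
contingency_test <- function(tab, method = c("auto", "fisher", "chisq"),
                             expected_min = 5) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) abort("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) abort("empty margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (any(expected < expected_min)) "fisher" else "chisq"
  if (method == "fisher") {
    list(p.value = stats::fisher.test(tab)$p.value, method = "fisher")
  } else {
    correct <- all(dim(tab) == c(2, 2))
    list(p.value = stats::chisq.test(tab, correct = correct)$p.value,
         method = if (correct) "chisq_yates" else "chisq")
  }
}

#' Correlation between two variables with the zero-value rule
#'
#' Pearson correlation by default; Spearman rank correlation is selected
#' automatically (method `"auto"`) when either unlogged input contains
#' zeros, since zeros make the log-scale Pearson coefficient undefined.
#'
#' @param x,y numeric vectors of equal length (unlogged values for `"auto"`).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return list with `estimate` and `method`.
#' @export
correlation_assoc <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("fewer than 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("correlation undefined for a constant vector")
  if (method == "auto")
    method <- if (any(x == 0) || any(y == 0)) "spearman" else "pearson"
  list(estimate = stats::cor(x, y, method = method), method = method)
}

#' Secretome-based multivariate distance between paired tissues
#'
#' Per patient, the Euclidean distance between the tumor and juxta-tumor
#' profiles on natural-log concentrations, over all analytes non-missing on
#' both sides. Uses the full analyte panel: the low-detection exclusion does
#' not apply to this distance.
#'
#' @param cohort a linear-scale, LOD-imputed [paired_cohort()] or
#'   [secretome_matrix()].
#' @return named numeric vector of distances (one per patient).
#' @export
secretome_distance <- function(cohort) {
  m <- if (inherits(cohort, "paired_cohort")) cohort$secretome else cohort
  stopifnot(inherits(m, "secretome_matrix"))
  if (m$scale != "linear") abort("distance is computed from the linear-scale matrix")
  ts <- tissue_split(m)
  diff2 <- (log(ts$T) - log(ts$J))^2
  n_obs <- rowSums(!is.na(diff2))
  if (any(n_obs == 0))
    abort("patient %s has no analyte observed in both tissues",
          rownames(diff2)[which(n_obs == 0)[1]])
  sqrt(rowSums(diff2, na.rm = TRUE))
}

#' Group patients by secretome-distance quantiles
#'
#' Cuts the distance distribution at its 0.15 and 0.85 quantiles (linear
#' interpolation of the empirical CDF, the standard type-7 definition):
#' `low` for d <= Q(0.15), `high` for d >= Q(0.85), `int` otherwise
#' (boundaries inclusive). If the two cuts collapse (degenerate
#' distribution) every patient is `int`.
#'
#' @param d named numeric vector of distances (>= 10 patients).
#' @param q_low,q_high quantile cut points, defaults 0.15 / 0.85.
#' @return object of class `distance_grouping`: data.frame with `patient_id`,
#'   `distance`, `group`; attributes `cut_low`, `cut_high`.
#' @export
distance_groups <- function(d, q_low = 0.15, q_high = 0.85) {
  if (length(d) < 10) abort("at least 10 patients required")
  cuts <- stats::quantile(d, c(q_low, q_high), type = 7, names = FALSE)
  if (cuts[1] == cuts[2]) {
    group <- rep("int", length(d))
  } else {
    group <- ifelse(d <= cuts[1], "low", ifelse(d >= cuts[2], "high", "int"))
  }
  out <- data.frame(patient_id = names(d) %||% seq_along(d), distance = unname(d),
                    group = group, stringsAsFactors = FALSE)
  attr(out, "cut_low") <- cuts[1]; attr(out, "cut_high") <- cuts[2]
  class(out) <- c("distance_grouping", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
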