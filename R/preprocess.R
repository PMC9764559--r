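# Detection-limit imputation, log transformation and low-detection exclusion.
#
# Censored immunoassay concentrations are not missing at random: a cell below
# the batch's lower limit of detection carries the information "less than
# LOD". The imputation rules replace censored cells by a single common value
# per analyte so that downstream log-scale analyses can use them, while the
# censor flags are preserved so any analysis can still distinguish imputed
# cells from measured ones.

#' Impute detection-limit censored cells
#'
#' For each analyte, every `below_lod` cell receives the common value
#' 0.5 x mean(lower limits of the batches of that analyte that contain at
#' least one out-of-range sample); every `above_lod` cell receives the
#' maximum of the analyte's upper limits over batches. Flags are preserved.
#' The operation is idempotent.
#'
#' @param m a linear-scale [secretome_matrix()] with censor flags populated.
#' @param lod a [lod_table()].
#' @param batch_rule which batches define the lower-imputation mean:
#'   `"below"` (default) — batches where the analyte has at least one
#'   below-LOD sample; `"any"` — batches with any out-of-range (below or
#'   above) sample for that analyte.
#' @return the imputed `secretome_matrix`; attribute `imputed_counts` records
#'   per-analyte numbers of imputed cells.
#' @export
impute_detection_limits <- function(m, lod, batch_rule = c("below", "any")) {
  stopifnot(inherits(m, "secretome_matrix"), m$scale == "linear")
  batch_rule <- match.arg(batch_rule)
  counts <- data.frame(analyte = analytes(m), below = 0L, above = 0L)
  for (j in seq_along(analytes(m))) {
    a <- analytes(m)[j]
    below <- m$flags[, j] == "below_lod"
    above <- m$flags[, j] == "above_lod"
    rows <- lod[lod$analyte == a, ]
    if (any(below)) {
      oor <- if (batch_rule == "below") below else below | above
      batches <- unique(m$samples$batch[oor])
      lims <- rows$lower[rows$batch %in% batches]
      if (!length(lims))
        abort("below-LOD cells for analyte %s but no LOD row for its batches", a)
      m$values[below, j] <- 0.5 * mean(lims)
    }
    if (any(above)) {
      if (!nrow(rows))
        abort("above-LOD cells for analyte %s but no LOD rows", a)
      m$values[above, j] <- max(rows$upper)
    }
    counts$below[j] <- sum(below); counts$above[j] <- sum(above)
  }
  attr(m, "imputed_counts") <- counts
  m
}

#' Log-transform a secretome matrix
#'
#' Base-10 logs are the working scale of every analysis except the
#' secretome-based patient distance, which uses natural logs. Missing cells
#' stay missing.
#'
#' @param m a linear-scale [secretome_matrix()] (all non-missing values > 0,
#'   i.e. after LOD imputation).
#' @param base `10` (default) or `exp(1)`.
#' @return a `secretome_matrix` with `scale` `"log10"` or `"ln"`.
#' @export
log_transform <- function(m, base = 10) {
  stopifnot(inherits(m, "secretome_matrix"))
  if (m$scale != "linear") abort("matrix is already on the %s scale", m$scale)
  bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    abort("non-positive value at sample %s, analyte %s",
          rownames(m$values)[bad[1, 1]], colnames(m$values)[bad[1, 2]])
  if (isTRUE(all.equal(base, 10))) {
    m$values <- log10(m$values); m$scale <- "log10"
  } else if (isTRUE(all.equal(base, exp(1)))) {
    m$values <- log(m$values); m$scale <- "ln"
  } else abort("base must be 10 or e")
  m
}

#' Exclude analytes detected in too few juxta-tumor samples
#'
#' An analyte is excluded when its in-range detection rate among juxta-tumor
#' samples is strictly below `threshold` (default 5%). The rate denominator
#' counts non-missing J cells only: bead-aggregation dropout is assay
#' failure, not non-detection. Excluded analytes are dropped from every
#' multiparametric analysis except the secretome-based distance, which keeps
#' the full panel.
#'
#' @param m a [secretome_matrix()] (any scale; flags are what matters).
#' @param threshold detection-rate threshold, default `0.05`.
#' @return list with `retained`, `excluded` (analyte name vectors) and
#'   `rates` (named detection rates).
#' @export
low_detection_filter <- function(m, threshold = 0.05) {
  stopifnot(inherits(m, "secretome_matrix"))
  jrows <- m$samples$tissue == "J"
  if (!any(jrows)) abort("no juxta-tumor samples: detection rates are undefined")
  fl <- m$flags[jrows, , drop = FALSE]
  denom <- colSums(fl != "missing")
  rates <- ifelse(denom > 0, colSums(fl == "in_range") / denom, 0)
  names(rates) <- analytes(m)
  excluded <- analytes(m)[rates < threshold]
  list(retained = setdiff(analytes(m), excluded), excluded = excluded, rates = rates)
}

#' Subset a secretome matrix to a set of analytes
#' @param m a [secretome_matrix()].
#' @param keep character vector of analyte names to keep.
#' @return the subsetted matrix.
#' @export
select_analytes <- function(m, keep) {
  missing_a <- setdiff(keep, analytes(m))
  if (length(missing_a)) abort("unknown analyte(s): %s", paste(missing_a, collapse = ", "))
  m$values <- m$values[, keep, drop = FALSE]
  m$flags <- m$flags[, keep, drop = FALSE]
  m
}
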