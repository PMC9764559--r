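#' Secretome concentration matrix with censoring flags
#'
#' The central data container of the pipeline: a samples x analytes matrix of
#' concentrations (pg/mL) together with per-sample metadata (patient, tissue,
#' assay batch) and a per-cell censoring flag. Cells can be `in_range`,
#' `below_lod` / `above_lod` (outside the batch's detection limits), or
#' `missing` (bead aggregation — assay dropout, distinct from censoring).
#'
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `tissue` (`"T"` tumor / `"J"` juxta-tumor) and `batch`; one row per
#'   sample, aligned with the rows of `values`.
#' @param values numeric matrix (samples x analytes) of concentrations in
#'   pg/mL; `NA` where the cell is censored without a reported value or
#'   missing. Column names are the analyte names.
#' @param flags character matrix of the same dimension with entries in
#'   `c("in_range", "below_lod", "above_lod", "missing")`.
#' @param scale concentration scale of `values`: `"linear"` (pg/mL, the
#'   storage scale), `"log10"` or `"ln"` after [log_transform()].
#' @return an object of class `secretome_matrix`.
#' @export
secretome_matrix <- function(samples, values, flags = NULL, scale = "linear") {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "patient_id", "tissue", "batch")
  if (!all(required %in% names(samples)))
    abort("samples must have columns %s", paste(required, collapse = ", "))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(samples))
    abort("values has %d rows but samples has %d", nrow(values), nrow(samples))
  if (is.null(colnames(values))) abort("values must have analyte column names")
  if (is.null(flags)) {
    flags <- matrix(ifelse(is.na(values), "missing", "in_range"),
                    nrow(values), ncol(values), dimnames = dimnames(values))
  }
  flags <- as.matrix(flags)
  if (!identical(dim(flags), dim(values)))
    abort("flags and values dimensions differ")
  dimnames(flags) <- dimnames(values)
  bad <- setdiff(unique(as.vector(flags)), c("in_range", "below_lod", "above_lod", "missing"))
  if (length(bad)) abort("unknown censor flag(s): %s", paste(bad, collapse = ", "))
  if (!all(samples$tissue %in% c("T", "J")))
    abort("tissue must be 'T' or 'J'")
  if (anyDuplicated(samples[, c("patient_id", "tissue")]))
    abort("duplicate (patient_id, tissue) pair: each patient may contribute at most one sample per tissue")
  if (any(flags == "missing" & !is.na(values)))
    abort("cells flagged missing must have NA values")
  if (scale == "linear" && any(values[!is.na(values)] <= 0))
    abort("all non-missing linear-scale concentrations must be > 0")
  rownames(values) <- rownames(flags) <- samples$sample_id
  structure(
    list(samples = samples, values = values, flags = flags, scale = scale),
    class = "secretome_matrix"
  )
}

#' @export
print.secretome_matrix <- function(x, ...) {
  cat(sprintf(
    "<secretome_matrix> %d samples (%d T / %d J) x %d analytes [%s scale]\n",
    nrow(x$values), sum(x$samples$tissue == "T"), sum(x$samples$tissue == "J"),
    ncol(x$values), x$scale))
  tab <- table(factor(x$flags, c("in_range", "below_lod", "above_lod", "missing")))
  cat("  cells:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Analyte names of a secretome matrix
#' @param m a `secretome_matrix`.
#' @return character vector of analyte names.
#' @export
analytes <- function(m) colnames(m$values)

#' Split a paired matrix into per-tissue patient x analyte matrices
#'
#' Rows of both returned matrices are indexed by the union of patient ids,
#' with `NA` rows for patients lacking that tissue, so tumor and juxta values
#' are directly comparable row by row.
#'
#' @param m a `secretome_matrix`.
#' @return list with elements `T` and `J` (patient x analyte value matrices)
#'   and `flags_T`, `flags_J`.
#' @export
tissue_split <- function(m) {
  patients <- unique(m$samples$patient_id)
  pick <- function(tissue, what) {
    idx <- match(patients, m$samples$patient_id[m$samples$tissue == tissue])
    rows <- which(m$samples$tissue == tissue)[idx]
    out <- m[[what]][rows, , drop = FALSE]
    if (what == "flags") out[is.na(rows), ] <- "missing"
    rownames(out) <- patients
    out
  }
  list(T = pick("T", "values"), J = pick("J", "values"),
       flags_T = pick("T", "flags"), flags_J = pick("J", "flags"))
}

#' A paired cohort: secretome matrix plus clinical covariates
#'
#' @param secretome a [secretome_matrix()] with paired T/J samples.
#' @param clinical data.frame of per-patient clinical covariates with a
#'   `patient_id` column covering every patient in `secretome`.
#' @return an object of class `paired_cohort`.
#' @export
paired_cohort <- function(secretome, clinical) {
  stopifnot(inherits(secretome, "secretome_matrix"))
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(clinical)) abort("clinical needs a patient_id column")
  orphan <- setdiff(secretome$samples$patient_id, clinical$patient_id)
  if (length(orphan))
    abort("patients missing from clinical table: %s", paste(utils::head(orphan, 5), collapse = ", "))
  structure(list(secretome = secretome, clinical = clinical), class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d patients, %d clinical covariates\n",
              length(unique(x$secretome$samples$patient_id)), ncol(x$clinical) - 1L))
  print(x$secretome)
  invisible(x)
}
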