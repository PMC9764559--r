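# Delimited-table input/output for secretome, detection-limit and clinical
# tables. Dialect: UTF-8, one header row, comma- or tab-delimited (sniffed
# from the header line); "ND" (configurable) marks below-LOD cells; an empty
# cell marks a missing value (bead aggregation).

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

read_delim_table <- function(path) {
  utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    fileEncoding = "UTF-8")
}

#' Read a detection-limit table
#'
#' One row per (analyte, batch) with the assay's lower and upper detection
#' limits in pg/mL.
#'
#' @param path CSV/TSV file with columns `analyte`, `batch`, `lower`, `upper`.
#' @return data.frame of class `lod_table`.
#' @export
read_lod_table <- function(path) {
  d <- read_delim_table(path)
  required <- c("analyte", "batch", "lower", "upper")
  if (!all(required %in% names(d)))
    abort("LOD table must have columns %s", paste(required, collapse = ", "))
  d$lower <- as.numeric(d$lower)
  d$upper <- as.numeric(d$upper)
  lod_table(d)
}

#' Construct/validate a detection-limit table
#' @param d data.frame with columns `analyte`, `batch`, `lower`, `upper`.
#' @return the validated data.frame, classed `lod_table`.
#' @export
lod_table <- function(d) {
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  if (any(!is.finite(d$lower)) || any(!is.finite(d$upper)))
    abort("non-numeric detection limit")
  if (any(d$lower >= d$upper)) abort("lower limit must be < upper limit")
  if (anyDuplicated(d[, c("analyte", "batch")]))
    abort("duplicate (analyte, batch) row in LOD table")
  class(d) <- c("lod_table", "data.frame")
  d
}

lod_lookup <- function(lod, analyte, batch) {
  i <- which(lod$analyte == analyte & lod$batch == batch)
  if (!length(i)) return(NULL)
  lod[i, ]
}

#' Read a secretome concentration table
#'
#' Parses a delimited samples x analytes table into a [secretome_matrix()].
#' Metadata columns `sample_id`, `patient_id`, `tissue`, `batch` are required;
#' every remaining column is an analyte. Cells equal to `nd_token` are flagged
#' `below_lod` (value unset); empty cells are flagged `missing`; numeric cells
#' are compared against the batch's detection limits and flagged `below_lod` /
#' `above_lod` when out of range (the reported value is preserved), otherwise
#' `in_range`.
#'
#' @param path CSV/TSV file.
#' @param lod a [lod_table()] covering every (analyte, batch) in the file.
#' @param nd_token token marking below-detection cells (default `"ND"`).
#' @param above_token token marking above-detection cells without a reported
#'   value (default `"OOR>"`, the Bio-Plex out-of-range convention).
#' @return a [secretome_matrix()].
#' @export
read_secretome_table <- function(path, lod, nd_token = "ND",
                                 above_token = "OOR>") {
  d <- read_delim_table(path)
  meta_cols <- c("sample_id", "patient_id", "tissue", "batch")
  if (!all(meta_cols %in% names(d)))
    abort("secretome table must have columns %s", paste(meta_cols, collapse = ", "))
  analyte_cols <- setdiff(names(d), meta_cols)
  unknown <- setdiff(analyte_cols, unique(lod$analyte))
  if (length(unknown))
    abort("analyte column(s) absent from the LOD table: %s",
          paste(unknown, collapse = ", "))
  samples <- d[meta_cols]
  n <- nrow(d); p <- length(analyte_cols)
  values <- matrix(NA_real_, n, p, dimnames = list(samples$sample_id, analyte_cols))
  flags <- matrix("in_range", n, p, dimnames = dimnames(values))
  for (j in seq_len(p)) {
    a <- analyte_cols[j]
    raw <- trimws(d[[a]])
    is_nd <- raw == nd_token
    is_above <- raw == above_token
    is_empty <- raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is_nd & !is_above & !is_empty & is.na(num)
    if (any(bad))
      abort("non-numeric cell '%s' at row %d, column %s",
            raw[which(bad)[1]], which(bad)[1], a)
    flags[is_nd, j] <- "below_lod"
    flags[is_above, j] <- "above_lod"
    flags[is_empty, j] <- "missing"
    values[, j] <- ifelse(is_nd | is_above | is_empty, NA_real_, num)
    rows <- lod[lod$analyte == a, ]
    bi <- match(samples$batch, rows$batch)
    if (any(is.na(bi) & !is.na(values[, j])))
      abort("no LOD row for analyte %s in batch %s", a,
            samples$batch[which(is.na(bi) & !is.na(values[, j]))[1]])
    lo <- rows$lower[bi]; hi <- rows$upper[bi]
    obs <- !is.na(values[, j])
    flags[obs & values[, j] < lo, j] <- "below_lod"
    flags[obs & values[, j] > hi, j] <- "above_lod"
  }
  secretome_matrix(samples, values, flags)
}

#' Write a secretome matrix back to a delimited file
#'
#' Inverse of [read_secretome_table()]: `below_lod` cells without a value are
#' written as the ND token, missing cells as empty, everything else as the
#' stored number (full precision, so a write/read round trip is exact).
#'
#' @param m a linear-scale [secretome_matrix()].
#' @param path output file; extension `.tsv` selects tab separation.
#' @param nd_token below-LOD token.
#' @param above_token above-LOD token.
#' @return `path`, invisibly.
#' @export
write_secretome_table <- function(m, path, nd_token = "ND",
                                  above_token = "OOR>") {
  stopifnot(inherits(m, "secretome_matrix"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  cells <- matrix(format(m$values, digits = 17, trim = TRUE, scientific = FALSE),
                  nrow(m$values), ncol(m$values))
  cells[is.na(m$values)] <- ""
  cells[m$flags == "below_lod" & is.na(m$values)] <- nd_token
  cells[m$flags == "above_lod" & is.na(m$values)] <- above_token
  out <- cbind(m$samples, as.data.frame(cells, stringsAsFactors = FALSE))
  names(out) <- c(names(m$samples), colnames(m$values))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical covariate table
#'
#' One row per patient. Categorical levels are validated against the closed
#' level sets of the cohort description where a column is recognized
#' (molecular class, EE grade, Ki-67 class, yes/no covariates).
#'
#' @param path CSV/TSV file with a `patient_id` column.
#' @return data.frame.
#' @export
read_clinical_table <- function(path) {
  d <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!"patient_id" %in% names(d)) abort("clinical table needs a patient_id column")
  if (anyDuplicated(d$patient_id)) abort("duplicate patient_id in clinical table")
  closed <- list(
    molecular_class = c("HER2", "LUMA", "LUMB", "LUMHER2", "TN"),
    ee_grade = c("I", "II", "III"),
    ki67_class = c("<20", ">=20"),
    pregnancy = c("no", "yes"), menopause = c("no", "yes"),
    vascular_emboli = c("no", "yes")
  )
  for (col in intersect(names(closed), names(d))) {
    bad <- setdiff(stats::na.omit(unique(d[[col]])), closed[[col]])
    if (length(bad))
      abort("unknown level(s) in clinical column %s: %s", col, paste(bad, collapse = ", "))
  }
  d
}

#' Write a clinical table / generic CSV helper
#' @param d data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(d, path) {
  utils::write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
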