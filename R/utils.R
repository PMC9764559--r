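#' Derive a reproducible substream seed from a master seed
#'
#' Every source of randomness in the pipeline (synthetic cohort, train/test
#' split, imputation streams, CV folds) draws its own seed from one master
#' seed plus a stream name, so stages can be rerun in isolation and still
#' reproduce a full-pipeline run exactly.
#'
#' @param seed master seed (integer).
#' @param stream character stream name, e.g. `"split"`, `"imputation"`.
#' @return an integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer(((abs(seed) %% 1e6) * 1013L + h * 97L + 17L) %% 2147483647)
}

#' Significance codes for p-values
#'
#' Maps p-values to the star codes used throughout the comparison tables:
#' `NS` (> 0.05), `*` (<= 0.05), `**` (<= 0.01), `***` (<= 0.001). With
#' `dot = TRUE` an additional trend code `.` (<= 0.1) is used in place of
#' `NS` for 0.05 < p <= 0.1 (clinical-association tables).
#'
#' @param p numeric vector of p-values.
#' @param dot logical; include the `.` trend level.
#' @return character vector of codes.
#' @export
significance_code <- function(p, dot = FALSE) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0.001) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else if (dot && pi <= 0.1) "."
    else "NS"
  }, character(1))
}

# Internal: stop with a formatted message
abort <- function(...) stop(sprintf(...), call. = FALSE)

# Internal: roman labels I..V.. for cluster ordering
roman_labels <- function(k) as.character(utils::as.roman(seq_len(k)))
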