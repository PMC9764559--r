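# Shared fixtures, built in code. The default cohort and the full signature
# fit are expensive, so they are memoised and shared across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

default_cohort_fx <- function() memo("default_cohort", function()
  generate_cohort(default_cohort_config(), seed = 7))

# full study-condition fit: m = 30 imputations, full alpha grid
default_fit_fx <- function() memo("default_fit", function()
  fit_tumor_signature(default_cohort_fx()$cohort, default_cohort_fx()$lod,
                      seed = 11))

null_cohort_fx <- function() memo("null_cohort", function()
  generate_cohort(null_cohort_config(), seed = 13))

# a small hand-built paired cohort for io/preprocess unit tests:
# 3 patients x 2 batches x 3 analytes with every censoring situation
tiny_matrix_fx <- function() {
  samples <- data.frame(
    sample_id = c("P1_T", "P1_J", "P2_T", "P2_J", "P3_T", "P3_J"),
    patient_id = rep(c("P1", "P2", "P3"), each = 2),
    tissue = rep(c("T", "J"), 3),
    batch = c("B1", "B1", "B1", "B1", "B2", "B2"))
  values <- matrix(
    c(200, 100, 50, 25, 400, 80,      # A: all in range
      NA,  8,   NA, 9,   9,  NA,      # B: censored cells (below/above/missing)
      5,   6,   7,  8,   9,  10),     # C: in range
    nrow = 6, dimnames = list(samples$sample_id, c("A", "B", "C")))
  flags <- matrix("in_range", 6, 3, dimnames = dimnames(values))
  flags[1, "B"] <- "below_lod"; flags[3, "B"] <- "above_lod"
  flags[6, "B"] <- "missing"
  list(m = secretome_matrix(samples, values, flags),
       lod = lod_table(data.frame(
         analyte = rep(c("A", "B", "C"), each = 2),
         batch = rep(c("B1", "B2"), 3),
         lower = c(1, 1, 2, 4, 0.5, 0.5),
         upper = c(1000, 1000, 10, 12, 100, 100))))
}

# brute-force reference for the greedy correlation filter
brute_correlation_filter <- function(x, cutoff = 0.8) {
  cm <- abs(stats::cor(x)); diag(cm) <- 0
  keep <- colnames(cm)
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    if (length(keep) < 2 || max(sub) <= cutoff) return(keep)
    idx <- which(sub == max(sub), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    nm <- cbind(keep[idx[, 1]], keep[idx[, 2]])
    o <- order(nm[, 1], nm[, 2])
    a <- nm[o[1], 1]; b <- nm[o[1], 2]
    ma <- mean(sub[a, setdiff(keep, a)]); mb <- mean(sub[b, setdiff(keep, b)])
    drop <- if (ma > mb) a else if (mb > ma) b else max(a, b)
    keep <- setdiff(keep, drop)
  }
}

# brute-force Mann-Whitney AUC by pair counting
brute_auc <- function(scores, labels) {
  pos <- scores[labels == "T"]; neg <- scores[labels == "J"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# adjusted Rand index (for cluster-recovery checks)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab))); sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
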