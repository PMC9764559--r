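test_that("below-LOD cells get half the mean lower limit of out-of-range batches", {
  # analyte with below-LOD samples in batches with lower limits 2 and 4:
  # every below-LOD cell becomes (2 + 4) / 2 * 0.5 = 1.5
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        patient_id = paste0("P", 1:4),
                        tissue = c("T", "T", "J", "J"),
                        batch = c("B1", "B2", "B1", "B2"))
  values <- matrix(c(NA, NA, 50, 60), 4, 1, dimnames = list(samples$sample_id, "X"))
  flags <- matrix(c("below_lod", "below_lod", "in_range", "in_range"), 4, 1,
                  dimnames = dimnames(values))
  m <- secretome_matrix(samples, values, flags)
  lod <- lod_table(data.frame(analyte = "X", batch = c("B1", "B2", "B3"),
                              lower = c(2, 4, 100), upper = c(1000, 2000, 3000)))
  out <- impute_detection_limits(m, lod)
  expect_equal(unname(out$values[1:2, "X"]), c(1.5, 1.5))
  expect_equal(out$flags, m$flags)  # flags preserved

  # above-LOD cells get the maximum of the analyte's upper limits over batches
  flags2 <- flags; flags2[1, 1] <- "above_lod"
  m2 <- secretome_matrix(samples, values, flags2)
  out2 <- impute_detection_limits(m2, lod)
  expect_equal(unname(out2$values[1, "X"]), 3000)
})

test_that("LOD imputation is idempotent and leaves uncensored matrices unchanged", {
  fx <- tiny_matrix_fx()
  once <- impute_detection_limits(fx$m, fx$lod)
  twice <- impute_detection_limits(once, fx$lod)
  expect_identical(once$values, twice$values)
  expect_identical(once$flags, twice$flags)
  # below-LOD cell of analyte B (batch B1, lower 2): 0.5 * 2 = 1
  expect_equal(unname(once$values["P1_T", "B"]), 1)
  # above-LOD cell: max upper over batches = 12
  expect_equal(unname(once$values["P2_T", "B"]), 12)
  # missing cells remain missing
  expect_true(is.na(once$values["P3_J", "B"]))

  clean <- tiny_matrix_fx()$m
  clean$flags[] <- "in_range"; clean$values[is.na(clean$values)] <- 1
  expect_identical(impute_detection_limits(clean, fx$lod)$values, clean$values)
})

test_that("imputed below-LOD values sit below the in-range values of strict batches", {
  g <- generate_cohort(default_cohort_config(n_patients = 120), seed = 3)
  sec <- impute_detection_limits(g$cohort$secretome, g$lod)
  for (a in analytes(sec)) {
    below <- sec$flags[, a] == "below_lod"
    if (!any(below)) next
    imputed <- unique(sec$values[below, a])
    expect_length(imputed, 1)  # one common value per analyte
    strict <- g$lod$batch[g$lod$analyte == a & g$lod$lower >= imputed * 2]
    rows <- sec$flags[, a] == "in_range" & sec$samples$batch %in% strict
    if (any(rows)) expect_lt(imputed, min(sec$values[rows, a]))
  }
})

test_that("log transform handles both bases, missing cells and bad values", {
  fx <- tiny_matrix_fx()
  m <- impute_detection_limits(fx$m, fx$lod)
  lg <- log_transform(m, 10)
  expect_equal(unname(lg$values["P1_T", "A"]), log10(200))
  expect_true(is.na(lg$values["P3_J", "B"]))
  expect_equal(lg$scale, "log10")
  ln <- log_transform(m, exp(1))
  expect_equal(unname(ln$values["P1_J", "A"]), log(100))
  expect_error(log_transform(lg), "already")
  m$values[1, 1] <- -1
  expect_error(log_transform(m, 10), "non-positive")
  # spot values: 100 -> 2 in base 10, e -> 1 in base e
  m2 <- fx$m; m2$values[!is.na(m2$values)] <- 100
  expect_equal(unname(log_transform(m2, 10)$values[1, "A"]), 2)
  m2$values[!is.na(m2$values)] <- exp(1)
  expect_equal(unname(log_transform(m2, exp(1))$values[1, "A"]), 1)
})

test_that("low-detection exclusion uses a strict threshold over non-missing J cells", {
  n <- 100
  samples <- data.frame(sample_id = c(paste0("T", 1:5), paste0("J", 1:n)),
                        patient_id = c(paste0("P", 1:5), paste0("P", 1:n)),
                        tissue = c(rep("T", 5), rep("J", n)),
                        batch = "B1")
  mk <- function(n_detected) {
    flags <- c(rep("in_range", 5), rep("in_range", n_detected),
               rep("below_lod", n - n_detected))
    vals <- ifelse(flags == "in_range", 10, NA_real_)
    list(v = vals, f = flags)
  }
  four <- mk(4); five <- mk(5)
  values <- cbind(four$v, five$v)
  colnames(values) <- c("rare", "borderline")
  flags <- cbind(four$f, five$f); dimnames(flags) <- dimnames(values)
  m <- secretome_matrix(samples, values, flags)
  res <- low_detection_filter(m, 0.05)
  expect_equal(res$excluded, "rare")          # 4/100 < 5%
  expect_equal(res$retained, "borderline")    # exactly 5/100 is retained
  # missing cells leave the denominator: 4 detected of 80 non-missing = 5%
  flags[86:105, 1] <- "missing"; values[86:105, 1] <- NA
  m2 <- secretome_matrix(samples, values, flags)
  expect_equal(low_detection_filter(m2, 0.05)$excluded, character(0))
  # no juxta samples at all is an error
  tonly <- secretome_matrix(samples[1:5, ], values[1:5, , drop = FALSE],
                            flags[1:5, , drop = FALSE])
  expect_error(low_detection_filter(tonly), "juxta")
})

test_that("the six planted near-undetectable analytes are excluded on the default cohort", {
  g <- default_cohort_fx()
  res <- low_detection_filter(g$cohort$secretome)
  expect_setequal(res$excluded,
                  c("IL-9", "TPO", "IL-12p40", "TNF-b", "TSLP", "IL-21"))
  expect_length(res$retained, 49)
  # retention matches the planted detection rates analyte by analyte
  expect_setequal(res$retained, names(res$rates)[res$rates >= 0.05])
})
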