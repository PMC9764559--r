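test_that("tumor/juxta ratios are log10 fold-changes with exact back-transform", {
  fx <- tiny_matrix_fx()
  m <- impute_detection_limits(fx$m, fx$lod)
  rat <- tumor_juxta_ratios(m)
  # T = 200, J = 100 -> log10 fold 2
  expect_equal(unname(rat$values["P1", "A"]), log10(2))
  expect_equal(10^rat$values["P1", "A"] * m$values["P1_J", "A"],
               unname(m$values["P1_T", "A"]))
  # T = J gives exactly 0
  m2 <- m; m2$values[, "C"] <- 5;
  expect_equal(unname(tumor_juxta_ratios(m2)$values[, "C"]), rep(0, 3))
  # incomplete pairs yield missing cells; LOD-imputed sides are flagged
  expect_true(is.na(rat$values["P3", "B"]))
  expect_true(rat$imputed["P1", "B"])
  expect_false(rat$imputed["P1", "A"])
})

test_that("swapping tissue labels negates ratios and preserves the distance", {
  g <- generate_cohort(default_cohort_config(n_patients = 30), seed = 17)
  sec <- impute_detection_limits(g$cohort$secretome, g$lod)
  swapped <- sec
  swapped$samples$tissue <- ifelse(sec$samples$tissue == "T", "J", "T")
  expect_equal(tumor_juxta_ratios(swapped)$values, -tumor_juxta_ratios(sec)$values)
  expect_equal(secretome_distance(swapped), secretome_distance(sec))
})

test_that("paired t test matches hand computation and the one-sample oracle", {
  # differences (1, 2, 3): t = mean / (sd / sqrt(n)) = 2 / (1 / sqrt(3)) = 2 sqrt(3)
  x <- c(11, 22, 33); y <- c(10, 20, 30)
  res <- paired_t_test(x, y)
  expect_equal(res$statistic, 2 * sqrt(3))
  expect_equal(res$p.value, 2 * pt(2 * sqrt(3), df = 2, lower.tail = FALSE))
  # identical vectors: t = 0, p = 1, NS
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0); expect_equal(same$p.value, 1)
  expect_equal(same$code, "NS")
  # one-sample t test on differences is the same test
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(paired_t_test(a, b)$p.value, t.test(a - b)$p.value)
  # degenerate nonzero constant difference is flagged, not p-valued
  deg <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_error(paired_t_test(1:2, 2:3), "3 complete")
})

test_that("significance codes follow the star-code thresholds", {
  expect_equal(significance_code(c(0.2, 0.05, 0.03, 0.01, 0.0005)),
               c("NS", "*", "*", "**", "***"))
  expect_equal(significance_code(0.07, dot = TRUE), ".")
})

test_that("contingency test switches between Yates chi-squared and Fisher", {
  # balanced 2x2 -> p = 1 by symmetry under either test
  expect_equal(contingency_test(matrix(c(10, 10, 10, 10), 2), "fisher")$p.value, 1)
  expect_equal(contingency_test(matrix(c(10, 10, 10, 10), 2))$p.value, 1)
  # small expected counts trigger the exact test automatically
  expect_equal(contingency_test(matrix(c(8, 1, 1, 8), 2))$method, "fisher")
  # perfectly diagonal table vs exhaustive hypergeometric enumeration
  tab <- matrix(c(20, 0, 0, 20), 2)
  res2 <- contingency_test(tab, "fisher")
  probs <- dhyper(0:20, 20, 20, 20)
  p_exact <- sum(probs[probs <= dhyper(20, 20, 20, 20) * (1 + 1e-7)])
  expect_equal(res2$p.value, p_exact)
  # balanced table with expected counts >= 5 -> Yates statistic 0, p = 1
  res3 <- contingency_test(matrix(c(50, 50, 50, 50), 2))
  expect_equal(res3$method, "chisq_yates")
  expect_equal(res3$p.value, 1)
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("correlation helper applies the Pearson/Spearman zero rule", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_assoc(x, 2 * x)$estimate, 1)
  rev_ranked <- c(4, 3, 2, 1)
  expect_equal(correlation_assoc(x, rev_ranked, "spearman")$estimate, -1)
  # rank formula: 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d^2 sum = 4
  expect_equal(correlation_assoc(c(1, 2, 3, 4), c(2, 1, 4, 3), "spearman")$estimate, 0.6)
  # zeros in the unlogged input switch the auto rule to Spearman
  expect_equal(correlation_assoc(c(0, 1, 2, 3), c(5, 6, 9, 30))$method, "spearman")
  expect_equal(correlation_assoc(c(2, 1, 2, 3), c(5, 6, 9, 30))$method, "pearson")
  expect_error(correlation_assoc(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("secretome distance equals the brute-force natural-log oracle", {
  # single analyte with T = e * J -> distance exactly 1
  samples <- data.frame(sample_id = c("P1_T", "P1_J"), patient_id = "P1",
                        tissue = c("T", "J"), batch = "B1")
  m <- secretome_matrix(samples, matrix(c(exp(1) * 5, 5), 2, 1,
                                        dimnames = list(samples$sample_id, "A")))
  expect_equal(unname(secretome_distance(m)), 1)
  # identical profiles -> 0
  m0 <- secretome_matrix(samples, matrix(c(5, 5), 2, 1,
                                         dimnames = list(samples$sample_id, "A")))
  expect_equal(unname(secretome_distance(m0)), 0)
  # random 5-analyte profiles vs an explicit loop
  g <- generate_cohort(default_cohort_config(n_patients = 12), seed = 2)
  sec <- impute_detection_limits(g$cohort$secretome, g$lod)
  sec <- select_analytes(sec, analytes(sec)[1:5])
  d <- secretome_distance(sec)
  ts <- tissue_split(sec)
  for (p in names(d)) {
    acc <- 0
    for (a in analytes(sec)) {
      ta <- ts$T[p, a]; ja <- ts$J[p, a]
      if (!is.na(ta) && !is.na(ja)) acc <- acc + (log(ta) - log(ja))^2
    }
    expect_equal(unname(d[p]), sqrt(acc))
  }
})

test_that("distance grouping cuts at the 0.15/0.85 quantiles", {
  d <- setNames(sample(seq(0.01, 1, length.out = 100)), paste0("P", 1:100))
  dg <- distance_groups(d)
  expect_equal(as.vector(table(factor(dg$group, c("low", "int", "high")))),
               c(15, 70, 15))
  # all-equal distances collapse to a single "int" group
  expect_true(all(distance_groups(rep(1, 20))$group == "int"))
  # n = 20 distinct values vs direct quantile computation
  set.seed(8); d20 <- rlnorm(20)
  dg20 <- distance_groups(d20)
  q <- quantile(d20, c(0.15, 0.85), type = 7, names = FALSE)
  expect_equal(dg20$group,
               ifelse(d20 <= q[1], "low", ifelse(d20 >= q[2], "high", "int")))
  expect_error(distance_groups(1:5), "10")
})

test_that("distance-group proportions converge to 15/70/15 on continuous data", {
  set.seed(123)
  d <- rlnorm(1000, 1, 0.4)
  dg <- distance_groups(d)
  props <- table(dg$group) / 1000
  expect_lt(abs(props[["low"]] - 0.15), 0.02)
  expect_lt(abs(props[["int"]] - 0.70), 0.02)
  expect_lt(abs(props[["high"]] - 0.15), 0.02)
})

test_that("ratio medians track the planted effect ordering on the default cohort", {
  g <- default_cohort_fx()
  sec <- impute_detection_limits(g$cohort$secretome, g$lod)
  keep <- low_detection_filter(sec)$retained
  rat <- tumor_juxta_ratios(sec)
  med <- apply(rat$values[, keep], 2, median, na.rm = TRUE)
  truth <- g$truth$analytes
  planted <- truth$delta[match(keep, truth$analyte)]
  expect_gt(cor(med, planted, method = "spearman"), 0.9)
})

test_that("type-I error of the paired test is controlled on the null cohort", {
  g <- null_cohort_fx()
  sec <- impute_detection_limits(g$cohort$secretome, g$lod)
  keep <- low_detection_filter(sec)$retained
  cmp <- comparison_table(sec, analyte_set = keep)
  frac <- mean(cmp$p.value <= 0.05, na.rm = TRUE)
  # tests share patient-level factors, so the band is wider than pure
  # binomial noise around the nominal 5%
  expect_lt(frac, 0.15)
})
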