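test_that("train/test split is a deterministic patient-level partition", {
  pats <- sprintf("P%03d", 1:422)
  sp <- split_train_test(pats, 0.7, seed = 1)
  expect_length(sp$train, 296)
  expect_length(sp$test, 126)
  expect_setequal(c(sp$train, sp$test), pats)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(pats, 0.7, seed = 1))
  expect_false(identical(sp$test, split_train_test(pats, 0.7, seed = 2)$test))
  expect_error(split_train_test(pats, 1.2), "fraction")
})

test_that("near-zero-variance filter implements the 19/10% rule", {
  n <- 100
  x <- data.frame(
    constant = rep(1, n),
    lumpy = c(rep(0, 97), 1, 2, 3),         # freq ratio 97 > 19, 4% unique
    continuous = rnorm(n),
    frequent_but_diverse = rep(1:20, 5))    # freq ratio 1, retained
  expect_setequal(near_zero_variance_filter(x),
                  c("continuous", "frequent_but_diverse"))
  expect_error(near_zero_variance_filter(data.frame(k = rep(1, 5))), "near-zero")
})

test_that("correlation filter removes twins and matches the brute-force rule", {
  set.seed(11)
  base <- rnorm(60)
  x <- cbind(a = base, b = base, c = rnorm(60))
  kept <- correlation_filter(x, 0.8)
  expect_true("c" %in% kept)
  expect_length(setdiff(kept, "c"), 1)      # exactly one twin survives
  # nothing removed when all |r| below the cutoff
  set.seed(12)
  indep <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, letters[1:5]))
  expect_setequal(correlation_filter(indep, 0.8), letters[1:5])
  # random correlated 6-variable instances match the reference implementation
  for (s in 1:10) {
    set.seed(100 + s)
    z <- matrix(rnorm(40 * 3), 40, 3)
    xx <- cbind(z[, 1], z[, 1] + rnorm(40, 0, 0.2), z[, 2],
                z[, 2] + rnorm(40, 0, 0.3), z[, 3], rnorm(40))
    colnames(xx) <- paste0("v", 1:6)
    expect_identical(correlation_filter(xx, 0.6), brute_correlation_filter(xx, 0.6))
  }
})

test_that("multiple imputation preserves observed cells and the PMM support", {
  set.seed(21)
  n <- 80
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  df$y <- df$x1 + rnorm(n, 0, 0.5)
  df$y[1:10] <- NA
  # no missing cells: m identical copies
  imp0 <- multiple_impute(df[complete.cases(df), ], m = 3, seed = 1)
  expect_identical(imp0$completions[[1]], imp0$completions[[3]])
  # PMM with donor pool 1: every imputed value is an observed value
  imp1 <- multiple_impute(df, forced = "x1", m = 2, maxit = 3, seed = 2, donors = 1)
  for (cmp in imp1$completions) {
    expect_true(all(cmp$y[1:10] %in% df$y[-(1:10)]))
    expect_identical(cmp$y[-(1:10)], df$y[-(1:10)])  # observed untouched
    expect_identical(cmp$x1, df$x1)
  }
  # completions differ between imputations but share a seed-determined stream
  impa <- multiple_impute(df, forced = "x1", m = 2, maxit = 3, seed = 3)
  impb <- multiple_impute(df, forced = "x1", m = 2, maxit = 3, seed = 3)
  expect_identical(impa$completions, impb$completions)
  expect_false(identical(impa$completions[[1]]$y, impa$completions[[2]]$y))
  # binary categorical targets are imputed onto the original levels
  df$grp <- ifelse(df$x1 + rnorm(n) > 0, "hi", "lo")
  df$grp[5:12] <- NA
  imp2 <- multiple_impute(df, forced = "x1", m = 2, maxit = 3, seed = 4)
  expect_true(all(imp2$completions[[1]]$grp %in% c("hi", "lo")))
})

test_that("MCAR deletion is recovered to within sampling error after imputation", {
  g <- generate_cohort(default_cohort_config(n_patients = 150), seed = 19)
  sec <- impute_detection_limits(g$cohort$secretome, g$lod)
  lg <- log_transform(select_analytes(sec, c("IL-6", "CXCL8", "MMP2", "HGF",
                                             "Adiponectin", "VEGF")), 10)
  x <- lg$values[, ]; x <- x[complete.cases(x), ]
  full_means <- colMeans(x)
  set.seed(23)
  holed <- x
  holed[cbind(sample(nrow(x), 90, TRUE), sample(ncol(x), 90, TRUE))] <- NA
  imp <- multiple_impute(as.data.frame(holed), m = 10, maxit = 5, seed = 5)
  pooled_means <- colMeans(Reduce(`+`, lapply(imp$completions, as.matrix)) / 10)
  se <- apply(x, 2, sd) / sqrt(nrow(x))
  expect_true(all(abs(pooled_means - full_means) < 3 * se))
})

test_that("elastic-net CV fit matches a Newton ridge oracle at alpha ~ 0", {
  set.seed(31)
  n <- 200
  x <- cbind(s1 = rnorm(n), s2 = rnorm(n))
  y <- ifelse(x[, 1] * 2 + x[, 2] + rnorm(n, 0, 0.5) > 0, "T", "J")
  fit <- fit_elastic_net_cv(x, y, alpha = 1e-3, patient_ids = seq_len(n),
                            nfolds = 5, seed = 1)
  # Newton iterations on the ridge-penalized logistic likelihood at the
  # lambda the CV chose (glmnet objective: mean loglik + lambda/2 * ||b||^2)
  xs <- scale(x); yb <- as.numeric(y == "T")
  beta <- rep(0, 3); X <- cbind(1, xs); lam <- fit$lambda * (1 - 1e-3)
  for (i in 1:100) {
    eta <- drop(X %*% beta); p <- plogis(eta); w <- p * (1 - p)
    grad <- crossprod(X, p - yb) / n + lam * c(0, beta[-1])
    hess <- crossprod(X * w, X) / n + diag(c(0, lam, lam))
    beta <- beta - solve(hess, grad)
  }
  # tolerance covers glmnet's convergence threshold and the vanishing L1 part
  expect_equal(unname(fit$coef_std), beta[-1], tolerance = 2e-3)
  expect_equal(fit$intercept_std, beta[1], tolerance = 2e-3)
  # raw-scale coefficients reproduce the same scores
  sc_std <- fit$intercept_std + drop(xs %*% fit$coef_std)
  sc_raw <- fit$intercept_raw + drop(x %*% fit$coef_raw)
  expect_equal(sc_std, sc_raw)
  expect_error(fit_elastic_net_cv(x, rep("T", n), alpha = 0.5,
                                  patient_ids = seq_len(n)), "both classes")
})

test_that("a planted dominant analyte earns the largest coefficient", {
  set.seed(33)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("a", 1:6)))
  y <- ifelse(x[, 3] * 3 + rnorm(n, 0, 0.8) > 0, "T", "J")
  fit <- fit_elastic_net_cv(x, y, alpha = 0.5, patient_ids = seq_len(n),
                            nfolds = 5, seed = 2)
  expect_equal(names(which.max(abs(fit$coef_std))), "a3")
})

test_that("alpha selection follows the AUC / accuracy / sparsity tie-break", {
  # grid of one value is returned as-is
  set.seed(35)
  n <- 120
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("a", 1:5)))
  y <- ifelse(x[, 1] + rnorm(n, 0, 0.7) > 0, "T", "J")
  foldid <- make_pair_folds(seq_len(n), 5, seed = 3)
  one <- select_alpha(list(x), y, grid = 0.7, foldid = foldid)
  expect_equal(one$alpha, 0.7)
  expect_error(select_alpha(list(x), y, grid = numeric(0), foldid = foldid),
               "empty")
  # deterministic given the fold assignment
  two <- select_alpha(list(x), y, grid = c(0.2, 0.8), foldid = foldid)
  again <- select_alpha(list(x), y, grid = c(0.2, 0.8), foldid = foldid)
  expect_identical(two$alpha, again$alpha)
  # identical AUC and accuracy but fewer parameters wins (synthetic metrics)
  fake <- data.frame(alpha = c(0.3, 0.9), auc = c(0.95, 0.95),
                     accuracy = c(0.9, 0.9), n_selected = c(12, 5))
  cand <- which(fake$auc >= max(fake$auc) - 0.005)
  cand <- cand[order(-fake$accuracy[cand], fake$n_selected[cand], -fake$alpha[cand])]
  expect_equal(fake$alpha[cand[1]], 0.9)
})

test_that("stability aggregation applies strict majority and median pooling", {
  mk <- function(coefs) {
    structure(list(coef_std = coefs, coef_raw = coefs / 2,
                   intercept_std = 0.5, intercept_raw = 0.25,
                   cv_auc = 0.9, cv_accuracy = 0.9,
                   n_selected = sum(coefs != 0)), class = "per_imputation_model")
  }
  # analyte "a" selected 16/30 (> 15, kept), "b" 15/30 (dropped)
  models <- c(
    replicate(15, mk(c(a = 1, b = 2, c = 0)), simplify = FALSE),
    replicate(1, mk(c(a = 2, b = 0, c = 0)), simplify = FALSE),
    replicate(14, mk(c(a = 0, b = 0, c = 0)), simplify = FALSE))
  sig <- aggregate_signature(models)
  expect_setequal(sig$analytes, "a")
  expect_equal(unname(sig$selection_counts["a"]), 16)
  expect_equal(unname(sig$selection_counts["b"]), 15)
  # median over selecting models only: coefficients {1, 2, 10} pool to 2
  models2 <- list(mk(c(a = 1)), mk(c(a = 2)), mk(c(a = 10)))
  expect_equal(unname(aggregate_signature(models2)$coef_std["a"]), 2)
  # all-zero models cannot aggregate
  none <- replicate(4, mk(c(a = 0)), simplify = FALSE)
  expect_error(aggregate_signature(none), "weaker penalty")
})

test_that("ROC-corner cutoff matches the brute force over all thresholds", {
  # perfectly separated scores reach sensitivity = specificity = 1
  cut <- choose_cutoff(c(0.1, 0.2, 0.8, 0.9), c("J", "J", "T", "T"))
  expect_equal(cut$score_cutoff, 0.5)
  expect_equal(cut$sensitivity, 1); expect_equal(cut$specificity, 1)
  expect_equal(cut$prob_cutoff, plogis(0.5))
  # random 50-sample instance vs exhaustive enumeration
  set.seed(41)
  sc <- rnorm(50); lb <- ifelse(rnorm(50) + sc > 0, "T", "J")
  res <- choose_cutoff(sc, lb)
  s <- sort(unique(sc)); cand <- (s[-1] + s[-length(s)]) / 2
  d2 <- vapply(cand, function(ct) {
    tpr <- mean(sc[lb == "T"] >= ct); fpr <- mean(sc[lb == "J"] >= ct)
    fpr^2 + (1 - tpr)^2
  }, numeric(1))
  expect_equal(min(d2), res$sensitivity * 0 + (1 - res$sensitivity)^2 +
                 (1 - res$specificity)^2)
  expect_true(res$score_cutoff %in% cand[d2 == min(d2)])
  expect_error(choose_cutoff(rep(1, 4), c("T", "T", "J", "J")), "degenerate")
})

test_that("evaluation metrics are exact and AUC equals Mann-Whitney counting", {
  mk_model <- function() structure(list(analytes = "a", coef_raw = c(a = 1),
                                        coef_std = c(a = 1), intercept_raw = 0,
                                        intercept_std = 0, m = 1, alpha = 1,
                                        score_cutoff = 0, prob_cutoff = 0.5),
                                   class = "signature_model")
  x <- matrix(c(-2, -1, 1, 2), 4, 1, dimnames = list(NULL, "a"))
  ev <- evaluate_classifier(mk_model(), x, c("J", "J", "T", "T"))
  expect_equal(ev$accuracy, 1); expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1); expect_equal(ev$specificity, 1)
  expect_equal(unname(ev$confusion["T", "T"]), 2)
  # AUC identity with brute-force pair counting on a noisy instance,
  # cross-checked against an independent ROC implementation
  set.seed(43)
  sc <- rnorm(200); lb <- ifelse(sc + rnorm(200) > 0, "T", "J")
  ev2 <- evaluate_classifier(mk_model(), labels = lb, scores = sc, cutoff = 0)
  expect_equal(ev2$auc, brute_auc(sc, lb))
  expect_equal(ev2$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("J", "T"),
                                              direction = "<", quiet = TRUE))))
  # label permutation gives chance-level AUC
  set.seed(44)
  ev3 <- evaluate_classifier(mk_model(), labels = sample(lb), scores = sc,
                             cutoff = 0)
  expect_lt(abs(ev3$auc - 0.5), 0.08)
  expect_error(evaluate_classifier(mk_model(), x[, 0, drop = FALSE],
                                   c("T", "J", "T", "J")), "lacks")
})

test_that("clinical ANOVA matches the sum-of-squares oracle and flags effects", {
  clin <- data.frame(patient_id = paste0("P", 1:6),
                     grp = rep(c("a", "b"), each = 3))
  sc <- setNames(c(1, 2, 3, 4, 5, 6), clin$patient_id)
  res <- clinical_association(sc, clin, "grp")
  # SSB = 13.5 (df 1), SSW = 4 (df 4) -> F = 13.5, p from F(1, 4)
  expect_equal(res$F, 13.5)
  expect_equal(res$p.value, pf(13.5, 1, 4, lower.tail = FALSE))
  # identical group means: F = 0, p = 1
  sc2 <- setNames(c(1, 2, 3, 1, 2, 3), clin$patient_id)
  res2 <- clinical_association(sc2, clin, "grp")
  expect_equal(res2$F, 0); expect_equal(res2$p.value, 1)
  # single-level features are skipped with a warning
  clin$flat <- "same"
  expect_warning(out <- clinical_association(sc, clin, c("grp", "flat")),
                 "skipped")
  expect_equal(out$feature, "grp")
})

test_that("a planted pregnancy effect on the tumor score is flagged by ANOVA", {
  cfg <- default_cohort_config(n_patients = 250)
  cfg$clinical_effects$pregnancy_yes <- 0.3
  g <- generate_cohort(cfg, seed = 47)
  fit <- fit_tumor_signature(g$cohort, g$lod, seed = 3, m = 5,
                             alpha_grid = 1.0)
  row <- fit$clinical_assoc[fit$clinical_assoc$feature == "pregnancy", ]
  expect_lte(row$p.value, 0.05)
})
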