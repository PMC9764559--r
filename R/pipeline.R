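# One-call orchestration of the full analysis: preprocessing, paired
# comparison, unsupervised structure, signature. Writes every figure-analog
# table plus a run manifest with checksums, so a rerun with the same config
# and seed is verifiably identical.

#' Build a pipeline run configuration
#'
#' Exactly one of `paths` (real input tables) or `synthetic` (a
#' [default_cohort_config()]-style generator config) must be given.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed.
#' @param paths optional list with `secretome`, `lod`, `clinical` file paths.
#' @param synthetic optional `synthetic_config`.
#' @param k_clusters metamolecule cluster count, default 5.
#' @param pca_rank imputation rank for PCA completion, default 2.
#' @param signature list of overrides passed to [fit_tumor_signature()]
#'   (e.g. `m`, `maxit`, `alpha_grid`).
#' @param run_signature logical; the signature stage is the expensive one.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, paths = NULL, synthetic = NULL,
                       k_clusters = 5, pca_rank = 2, signature = list(),
                       run_signature = TRUE) {
  if (is.null(paths) == is.null(synthetic))
    abort("exactly one of paths/synthetic must be given")
  if (!is.null(paths) && !all(c("secretome", "lod", "clinical") %in% names(paths)))
    abort("paths must name secretome, lod and clinical files")
  structure(list(out_dir = out_dir, seed = seed, paths = paths,
                 synthetic = synthetic, k_clusters = k_clusters,
                 pca_rank = pca_rank, signature = signature,
                 run_signature = run_signature), class = "run_config")
}

#' Run the full secretome analysis pipeline
#'
#' Stages: load or generate the cohort; LOD imputation + low-detection
#' exclusion; per-analyte paired comparison table; secretome distance and
#' quantile groups; PCA of the sample secretome (iterative imputation of
#' missing cells) with tissue ellipses; ratio clustering into metamolecules;
#' the tumorness signature with evaluation and clinical association. Every
#' output is a CSV/JSON file under `cfg$out_dir`; the returned manifest
#' records the seed, per-stage timings and an md5 checksum per output.
#'
#' @param cfg a [run_config()].
#' @return the manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0); timings <- list()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      abort("stage '%s' failed: %s", name, conditionMessage(e)))
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    res
  }

  dat <- stage("load", function() {
    if (!is.null(cfg$synthetic)) {
      generate_cohort(cfg$synthetic, seed = substream_seed(cfg$seed, "synthetic-master"))
    } else {
      lod <- read_lod_table(cfg$paths$lod)
      list(cohort = paired_cohort(read_secretome_table(cfg$paths$secretome, lod),
                                  read_clinical_table(cfg$paths$clinical)),
           lod = lod, truth = NULL)
    }
  })
  cohort <- dat$cohort; lod <- dat$lod

  pre <- stage("preprocess", function() {
    sec <- impute_detection_limits(cohort$secretome, lod)
    ld <- low_detection_filter(sec)
    list(sec = sec, ld = ld)
  })
  emit("low_detection.csv", function(p) write_csv_table(
    data.frame(analyte = names(pre$ld$rates), detection_rate = pre$ld$rates,
               excluded = names(pre$ld$rates) %in% pre$ld$excluded), p))

  cmp <- stage("paired_comparison", function()
    comparison_table(pre$sec, analyte_set = pre$ld$retained))
  emit("comparison_table.csv", function(p) write_csv_table(cmp, p))

  dst <- stage("distance", function() {
    d <- secretome_distance(pre$sec)
    distance_groups(d)
  })
  emit("distance_groups.csv", function(p) write_csv_table(as.data.frame(dst), p))

  pca <- stage("pca", function() {
    lg <- log_transform(select_analytes(pre$sec, pre$ld$retained), 10)
    completed <- iterative_pca_impute(lg$values, ncp = cfg$pca_rank)
    res <- run_pca(completed)
    ell <- gaussian_ellipse(res$scores[, 1:2], lg$samples$tissue)
    list(res = res, ellipses = ell, tissue = lg$samples$tissue)
  })
  emit("pca_scores.csv", function(p) write_csv_table(
    data.frame(sample_id = rownames(pca$res$scores), tissue = pca$tissue,
               pca$res$scores[, 1:2]), p))
  emit("pca_contributions.csv", function(p) write_csv_table(
    data.frame(analyte = rownames(pca$res$contributions),
               pca$res$contributions[, 1:2]), p))
  emit("pca_ellipses.json", function(p) jsonlite::write_json(
    lapply(pca$ellipses, function(e) e[c("center", "cov", "radius", "degenerate")]),
    p, auto_unbox = TRUE, digits = NA))

  mm <- stage("metamolecules", function() {
    rat <- tumor_juxta_ratios(pre$sec)
    vals <- rat$values[, pre$ld$retained, drop = FALSE]
    completed <- iterative_pca_impute(vals, ncp = cfg$pca_rank)
    cl <- cluster_ratio_analytes(completed, k = cfg$k_clusters)
    list(clusters = cl, set = metamolecule_values(completed, cl$assignment))
  })
  emit("metamolecule_clusters.csv", function(p) write_csv_table(
    data.frame(analyte = names(mm$clusters$assignment),
               cluster = unname(mm$clusters$assignment)), p))
  emit("metamolecule_summary.csv", function(p) write_csv_table(mm$set$summary, p))
  emit("metamolecule_values.csv", function(p) write_csv_table(
    data.frame(patient_id = rownames(mm$set$values), mm$set$values,
               check.names = FALSE), p))

  fit <- NULL
  if (cfg$run_signature) {
    fit <- stage("signature", function()
      do.call(fit_tumor_signature,
              c(list(cohort = cohort, lod = lod, seed = substream_seed(cfg$seed, "signature")),
                cfg$signature)))
    emit("signature_model.json", function(p) jsonlite::write_json(
      fit$model[c("analytes", "coef_raw", "coef_std", "intercept_raw",
                  "intercept_std", "score_cutoff", "prob_cutoff", "alpha", "m")],
      p, auto_unbox = TRUE, digits = NA))
    emit("signature_performance.csv", function(p) write_csv_table(
      data.frame(set = c("train", "test"),
                 accuracy = c(fit$eval_train$accuracy, fit$eval_test$accuracy),
                 sensitivity = c(fit$eval_train$sensitivity, fit$eval_test$sensitivity),
                 specificity = c(fit$eval_train$specificity, fit$eval_test$specificity),
                 auc = c(fit$eval_train$auc, fit$eval_test$auc)), p))
    emit("roc_test.csv", function(p) write_csv_table(fit$eval_test$roc, p))
    emit("clinical_association.csv", function(p) write_csv_table(fit$clinical_assoc, p))
  }

  manifest <- list(
    seed = cfg$seed,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = timings,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, cohort = cohort, lod = lod,
                 truth = dat$truth, preprocess = pre, comparison = cmp,
                 distance = dst, pca = pca, metamolecules = mm, signature = fit))
}
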