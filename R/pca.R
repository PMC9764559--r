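# PCA with regularized iterative imputation of missing cells, variance /
# contribution summaries and Gaussian confidence ellipses.

#' Regularized iterative PCA imputation of missing cells
#'
#' Completes a numeric matrix by alternating a low-rank reconstruction with
#' refilling of the missing cells: initialize missing cells at column means,
#' then repeat (recenter, SVD, reconstruct at rank `ncp` with shrunk singular
#' values, refill missing cells) until the imputed cells change by less than
#' `tol` (RMS). Shrinkage multiplies each retained singular value d_c by
#' (d_c^2 - reg * sigma2) / d_c^2, where sigma2 is the mean residual squared
#' singular value — this damps noise-driven components and is what makes the
#' iteration robust at higher ranks. Observed cells are never altered.
#'
#' @param x numeric matrix with `NA` for missing cells (missing fraction
#'   below 50% per column).
#' @param ncp reconstruction rank (default 2).
#' @param reg regularization coefficient (default 1; 0 = plain EM-PCA).
#' @param tol convergence tolerance on the RMS change of imputed cells.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last delta.
#' @param trace logical; record the observed-cell reconstruction error per
#'   iteration in attribute `objective`.
#' @return the completed matrix (attributes `iterations`, and `objective`
#'   when `trace = TRUE`).
#' @export
iterative_pca_impute <- function(x, ncp = 2, reg = 1, tol = 1e-6,
                                 max_iter = 1000, trace = FALSE) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  frac <- colMeans(miss)
  if (any(frac >= 0.5)) {
    cn <- colnames(x) %||% as.character(seq_len(ncol(x)))
    abort("column %s has >= 50%% missing cells", cn[which(frac >= 0.5)[1]])
  }
  ncp <- min(ncp, nrow(x) - 1L, ncol(x))
  filled <- x
  mu0 <- colMeans(x, na.rm = TRUE)
  filled[miss] <- mu0[col(x)[miss]]
  objective <- numeric(0)
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(filled)
    xc <- sweep(filled, 2, mu)
    sv <- svd(xc)
    d <- sv$d
    q <- min(nrow(x) - 1L, ncol(x))
    sigma2 <- if (ncp < q) mean(d[(ncp + 1):q]^2) else 0
    shrunk <- pmax(d[seq_len(ncp)]^2 - reg * sigma2, 0) / d[seq_len(ncp)]
    recon <- sv$u[, seq_len(ncp), drop = FALSE] %*%
      (shrunk * t(sv$v[, seq_len(ncp), drop = FALSE]))
    recon <- sweep(recon, 2, mu, `+`)
    if (trace)
      objective <- c(objective, sum((recon[!miss] - x[!miss])^2))
    delta <- sqrt(mean((recon[miss] - filled[miss])^2))
    filled[miss] <- recon[miss]
    if (delta < tol) {
      attr(filled, "iterations") <- iter
      if (trace) attr(filled, "objective") <- objective
      return(filled)
    }
  }
  abort("iterative PCA imputation did not converge in %d iterations (last delta %.3g)",
        max_iter, delta)
}

#' Principal component analysis with variance and contribution summaries
#'
#' SVD-based PCA of a completed matrix; columns are centered and, by default,
#' scaled to unit variance (correlation PCA — the defensible default when
#' analytes span orders of magnitude in pg/mL). Per-component analyte
#' contributions are the squared loadings normalized to sum to 100%.
#'
#' @param x complete numeric matrix (samples x variables).
#' @param center,scale. passed to [stats::prcomp()]; defaults `TRUE`.
#' @return object of class `pca_result`: list with `scores`, `loadings`,
#'   `variance_fraction`, `contributions` (percent), `sdev`.
#' @export
run_pca <- function(x, center = TRUE, scale. = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs at least 2 samples")
  if (anyNA(x)) abort("PCA input must be complete; impute first")
  pc <- stats::prcomp(x, center = center, scale. = scale.)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- sweep(pc$rotation^2, 2, colSums(pc$rotation^2), `/`) * 100
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = varfrac, contributions = contrib,
                 sdev = pc$sdev, center = pc$center, scale = pc$scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), length(x$sdev),
              100 * x$variance_fraction[1], 100 * x$variance_fraction[2]))
  invisible(x)
}

#' Gaussian confidence ellipses for grouped 2-D scores
#'
#' Per group: the sample mean and covariance of the two score columns, with
#' ellipse semi-axes scaled by sqrt of the chi-squared(2) quantile at
#' `level`. A singular covariance (e.g. all points identical) is returned
#' with `degenerate = TRUE`.
#'
#' @param scores matrix/data.frame with two columns.
#' @param groups group labels (length = rows of `scores`).
#' @param level confidence level, default 0.95.
#' @return named list per group: `center`, `cov`, `radius`
#'   (`sqrt(qchisq(level, 2))`), `semi_axes` (sqrt eigenvalues x radius),
#'   `angle` (radians of the major axis), `degenerate`.
#' @export
gaussian_ellipse <- function(scores, groups, level = 0.95) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  out <- lapply(split(seq_len(nrow(scores)), groups), function(idx) {
    if (length(idx) < 3) abort("each group needs at least 3 samples")
    pts <- scores[idx, , drop = FALSE]
    cv <- stats::cov(pts)
    eg <- eigen(cv, symmetric = TRUE)
    radius <- sqrt(stats::qchisq(level, df = 2))
    degenerate <- any(eg$values <= .Machine$double.eps * max(1, eg$values[1]))
    list(center = colMeans(pts), cov = cv, radius = radius,
         semi_axes = sqrt(pmax(eg$values, 0)) * radius,
         angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
         degenerate = degenerate)
  })
  out
}
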