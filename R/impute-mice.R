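# Chained-equations multiple imputation with predictive mean matching for
# continuous variables and logistic draws for binary categorical variables.
# Predictor sets per incomplete variable are chosen by correlation screening
# (minimum absolute correlation against the variable or its missingness
# indicator), with a configurable list of forced-in predictors (clinical
# covariates and the outcome).

# Numeric encoding of a mixed data.frame: numerics pass through, 2-level
# categoricals become 0/1, k-level categoricals become k-1 dummies.
encode_numeric <- function(df) {
  cols <- list(); map <- list()
  for (v in names(df)) {
    x <- df[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
      map[[v]] <- v
    } else {
      x <- as.factor(x)
      lev <- levels(x)
      if (length(lev) < 2) abort("variable %s is constant", v)
      nm <- paste0(v, "=", lev[-1])
      for (i in seq_along(nm)) cols[[nm[i]]] <- as.numeric(x == lev[-1][i])
      for (i in seq_along(nm)) cols[[nm[i]]][is.na(x)] <- NA
      map[[v]] <- nm
    }
  }
  list(Z = do.call(cbind, cols), map = map)
}

# quickpred-style predictor screening: keep candidates whose absolute
# correlation with the target, or with the target's missingness indicator,
# reaches mincor; forced columns always kept.
screen_predictors <- function(Z, target_cols, candidate_cols, forced_cols,
                              mincor = 0.1) {
  y <- Z[, target_cols[1]]
  ind <- as.numeric(is.na(y))
  keep <- vapply(candidate_cols, function(u) {
    r1 <- suppressWarnings(stats::cor(y, Z[, u], use = "pairwise.complete.obs"))
    r2 <- if (stats::sd(ind) > 0)
      suppressWarnings(stats::cor(ind, Z[, u], use = "pairwise.complete.obs"))
    else 0
    max(abs(c(r1, r2)), na.rm = TRUE) >= mincor
  }, logical(1))
  chosen <- union(forced_cols, candidate_cols[keep & !is.na(keep)])
  setdiff(chosen, target_cols)
}

# Bayesian linear regression draw + predictive mean matching.
# Returns imputed values for the missing rows, each an observed donor value.
pmm_draw <- function(y, ry, X, donors = 5) {
  Xo <- X[ry, , drop = FALSE]; yo <- y[ry]
  Xm <- X[!ry, , drop = FALSE]
  p <- ncol(X)
  ridge <- diag(1e-5, p)
  XtX <- crossprod(Xo) + ridge
  beta_hat <- solve(XtX, crossprod(Xo, yo))
  resid <- yo - Xo %*% beta_hat
  df <- max(length(yo) - p, 1)
  sigma2_star <- sum(resid^2) / stats::rchisq(1, df)
  V <- sigma2_star * solve(XtX)
  beta_star <- beta_hat + t(chol((V + t(V)) / 2)) %*% stats::rnorm(p)
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(mu) {
    d <- abs(yhat_obs - mu)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    yo[sample(pool, 1)]
  }, numeric(1))
}

# Logistic regression draw for a binary (0/1-encoded) target.
logistic_draw <- function(y, ry, X) {
  Xo <- X[ry, , drop = FALSE]; yo <- y[ry]
  Xm <- X[!ry, , drop = FALSE]
  fit <- suppressWarnings(stats::glm.fit(Xo, yo, family = stats::binomial()))
  beta_hat <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  w <- fit$weights
  XtWX <- crossprod(Xo * sqrt(w)) + diag(1e-5, ncol(Xo))
  V <- solve(XtWX)
  beta_star <- beta_hat + t(chol((V + t(V)) / 2)) %*% stats::rnorm(ncol(Xo))
  pr <- stats::plogis(drop(Xm %*% beta_star))
  as.numeric(stats::runif(length(pr)) < pr)
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of a mixed table. Each incomplete variable
#' is regressed on a screened predictor set (minimum absolute correlation
#' `mincor` against the variable or its missingness indicator; `forced`
#' variables and the outcome always included), cycling `maxit` times per
#' imputation with independent random streams. Continuous variables are
#' imputed by predictive mean matching (Bayesian coefficient draw, then a
#' random draw among the `donors` observed values with nearest predicted
#' mean, so imputations stay on the observed support); binary categorical
#' variables by logistic-model draws. Observed cells are identical across
#' copies.
#'
#' @param df data.frame; numeric and categorical columns, `NA` for missing
#'   (missingness below 50% per column; multi-level categoricals must be
#'   complete).
#' @param forced character vector of column names always used as predictors
#'   (e.g. clinical covariates and the outcome).
#' @param m number of imputations (default 30).
#' @param maxit chained-equation cycles per imputation (default 10).
#' @param seed integer; stream `i` uses `substream_seed(seed, "mi-i")`.
#' @param mincor screening threshold (default 0.1).
#' @param donors PMM donor-pool size (default 5).
#' @return object of class `imputation_set`: list with `completions` (list of
#'   `m` completed data.frames), `predictors` (per incomplete variable),
#'   `m`, `maxit`, `seed`.
#' @export
multiple_impute <- function(df, forced = character(0), m = 30, maxit = 10,
                            seed = 1, mincor = 0.1, donors = 5) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad <- setdiff(forced, names(df))
  if (length(bad)) abort("forced predictor(s) not in table: %s", paste(bad, collapse = ", "))
  incomplete <- names(df)[vapply(df, anyNA, logical(1))]
  over <- incomplete[vapply(df[incomplete], function(x) mean(is.na(x)) >= 0.5, logical(1))]
  if (length(over)) abort("variable %s has >= 50%% missing cells", over[1])
  for (v in incomplete) {
    if (!is.numeric(df[[v]]) && length(unique(stats::na.omit(df[[v]]))) > 2)
      abort("multi-level categorical %s with missing cells is not supported", v)
  }
  if (!length(incomplete)) {
    return(structure(list(completions = replicate(m, df, simplify = FALSE),
                          predictors = list(), m = m, maxit = maxit, seed = seed),
                     class = "imputation_set"))
  }
  enc <- encode_numeric(df)
  Z <- enc$Z; map <- enc$map
  all_cols <- colnames(Z)
  forced_cols <- unlist(map[forced], use.names = FALSE)
  predictors <- list()
  for (v in incomplete) {
    cand <- setdiff(all_cols, unlist(map[v]))
    sel <- screen_predictors(Z, map[[v]], cand, forced_cols, mincor)
    if (!length(setdiff(sel, forced_cols)) && length(sel) < length(cand))
      warning(sprintf("no predictor passed screening for %s; using forced predictors only", v))
    if (!length(sel)) sel <- setdiff(forced_cols, unlist(map[v]))
    predictors[[v]] <- sel
  }
  miss <- lapply(incomplete, function(v) is.na(Z[, map[[v]][1]]))
  names(miss) <- incomplete
  binary_target <- !vapply(df[incomplete], is.numeric, logical(1))
  names(binary_target) <- incomplete

  completions <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(substream_seed(seed, paste0("mi-", i)))
    Zc <- Z
    for (v in incomplete) {        # init: random draws from observed values
      colv <- map[[v]][1]
      obs <- Zc[!miss[[v]], colv]
      Zc[miss[[v]], colv] <- sample(obs, sum(miss[[v]]), replace = TRUE)
    }
    for (iter in seq_len(maxit)) {
      for (v in incomplete) {
        colv <- map[[v]][1]
        X <- cbind(`(Intercept)` = 1, Zc[, predictors[[v]], drop = FALSE])
        ry <- !miss[[v]]
        Zc[miss[[v]], colv] <-
          if (binary_target[v]) logistic_draw(Zc[, colv], ry, X)
          else pmm_draw(Zc[, colv], ry, X, donors)
      }
    }
    out <- df
    for (v in incomplete) {
      colv <- map[[v]][1]
      if (binary_target[v]) {
        lev <- levels(as.factor(df[[v]]))
        out[[v]][miss[[v]]] <- lev[Zc[miss[[v]], colv] + 1]
      } else out[[v]][miss[[v]]] <- Zc[miss[[v]], colv]
    }
    completions[[i]] <- out
  }
  structure(list(completions = completions, predictors = predictors,
                 m = m, maxit = maxit, seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completions, maxit = %d, %d imputed variable(s)\n",
              x$m, x$maxit, length(x$predictors)))
  invisible(x)
}
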