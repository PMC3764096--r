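#' Fixed cross-validation partition
#'
#' A balanced random K-fold partition of lines, deterministic given the
#' seed. The same partition object is reused across platforms, traits
#' and subsampling replicates within one comparison run, so accuracy
#' differences are never due to fold composition.
#'
#' @param line_ids character vector of line identifiers.
#' @param K number of folds (default 10).
#' @param seed integer seed.
#' @return a `cv_partition`: list with `fold_of_line` (named integer
#'   vector), `K`, `seed`. Fold sizes differ by at most 1.
#' @export
make_partition <- function(line_ids, K = 10, seed = 1) {
  n <- length(line_ids)
  if (K > n) stop("K exceeds the number of lines")
  if (anyDuplicated(line_ids)) stop("duplicated line IDs")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(K), n))
  structure(list(fold_of_line = stats::setNames(fold, line_ids),
                 K = as.integer(K), seed = as.integer(seed)),
            class = "cv_partition")
}

#' Fit a GBLUP mixed model
#'
#' The genomic BLUP model `y = 1 mu + g + e` with `g ~ N(0, A sigma2_g)`
#' and `e ~ N(0, I sigma2_e)`, where `A` is the realized relationship
#' matrix. Variance components are REML estimates obtained by a
#' one-dimensional optimization over the variance ratio after spectral
#' decomposition of `A`. GEBVs are the BLUPs of `g`. By the
#' GBLUP/ridge-regression duality, the GEBVs equal `X beta_hat` from
#' ridge regression on marker effects with `lambda = sigma2_e/sigma2_g`
#' when `A = X X' / p`.
#'
#' @param y named numeric vector of phenotypes (line BLUEs); missing
#'   values are dropped. Names must appear in `rownames(A)`.
#' @param A relationship matrix covering at least the lines of `y`.
#' @return a `gblup` object: `mu`, `sigma2_g`, `sigma2_e`, `h2`
#'   (genomic heritability estimate), `gebv` (named, training lines),
#'   `alpha` (weights such that `A[new, train] %*% alpha` predicts new
#'   lines), `boundary` (TRUE if the variance ratio hit the optimizer
#'   boundary), `loglik` (restricted log-likelihood, up to a constant).
#' @export
gblup <- function(y, A) {
  if (is.null(names(y))) {
    if (length(y) != nrow(A)) stop("unnamed y must match A dimension")
    names(y) <- rownames(A)
  }
  y <- y[!is.na(y)]
  if (length(y) < 3) stop("need at least 3 non-missing phenotypes")
  if (!all(names(y) %in% rownames(A)))
    stop("phenotyped lines missing from A: ",
         paste(utils::head(setdiff(names(y), rownames(A))), collapse = ", "))
  ids <- names(y)
  At <- unclass(A)[ids, ids]
  n <- length(y)
  eg <- eigen((At + t(At)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-4 * max(abs(eg$values), 1))
    stop("A is not PSD within tolerance")
  core <- gblup_spectral(unname(y), pmax(eg$values, 0), eg$vectors)
  fit <- c(core[c("mu", "sigma2_g", "sigma2_e", "h2", "boundary", "loglik")],
           list(gebv = stats::setNames(core$gebv, ids),
                alpha = stats::setNames(core$alpha, ids),
                line_ids = ids))
  class(fit) <- "gblup"
  fit
}

## REML fit in the eigenbasis of A (values d, vectors U); shared by
## gblup() and the multi-trait cross-validation fast path so one
## decomposition serves every trait of a training fold.
gblup_spectral <- function(y, d, U) {
  n <- length(y)
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  if (stats::var(y) == 0)
    return(list(mu = y[1], sigma2_g = 0, sigma2_e = 0, h2 = 0,
                gebv = rep(0, n), alpha = rep(0, n),
                boundary = TRUE, loglik = NA_real_))
  # restricted log-likelihood profiled over delta = sigma2_e / sigma2_g
  reml_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    sxx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / sxx
    r <- yt - xt * mu
    s2g <- sum(w * r^2) / (n - 1)
    -0.5 * ((n - 1) * log(s2g) + sum(log(d + delta)) + log(sxx) + (n - 1))
  }
  opt <- stats::optimize(reml_ll, c(-12, 12), maximum = TRUE, tol = 1e-8)
  log_delta <- opt$maximum
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  sxx <- sum(w * xt^2)
  mu <- sum(w * xt * yt) / sxx
  r <- yt - xt * mu
  s2g <- sum(w * r^2) / (n - 1)
  s2e <- delta * s2g
  list(mu = mu, sigma2_g = s2g, sigma2_e = s2e, h2 = s2g / (s2g + s2e),
       gebv = drop(U %*% ((d * w) * r)),     # = A alpha, BLUP of g
       alpha = drop(U %*% (w * r)),          # = sigma2_g V^-1 (y - mu)
       boundary = log_delta > 11.5 || log_delta < -11.5,
       loglik = opt$objective)
}

#' Cross-validated accuracy for several traits sharing one partition
#'
#' Fast path for complete multi-trait phenotype matrices: per fold, the
#' training-block eigendecomposition is computed once and reused for the
#' REML fit of every trait. Traits with missing values fall back to
#' [cross_validate()] trait by trait. Results are identical to calling
#' [cross_validate()] per trait.
#'
#' @param Y lines x traits phenotype matrix with line-ID rownames.
#' @param A relationship matrix covering the lines of `Y`.
#' @param partition a [make_partition()] result.
#' @param pool as in [cross_validate()].
#' @return named numeric vector of accuracies, one per trait.
#' @export
cross_validate_traits <- function(Y, A, partition, pool = FALSE) {
  stopifnot(inherits(partition, "cv_partition"))
  if (anyNA(Y))
    return(vapply(colnames(Y), function(tr)
      as.numeric(cross_validate(Y[, tr], A, partition, pool = pool)),
      numeric(1)))
  ids <- rownames(Y)
  fold <- partition$fold_of_line[ids]
  preds <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  Au <- unclass(A)[ids, ids]
  for (k in seq_len(partition$K)) {
    val <- ids[fold == k]
    train <- setdiff(ids, val)
    eg <- eigen(Au[train, train], symmetric = TRUE)
    d <- pmax(eg$values, 0)
    for (tr in colnames(Y)) {
      core <- gblup_spectral(Y[train, tr], d, eg$vectors)
      preds[val, tr] <- drop(Au[val, train, drop = FALSE] %*% core$alpha)
    }
  }
  vapply(colnames(Y), function(tr) {
    if (pool) return(stats::cor(preds[, tr], Y[, tr]))
    mean(sapply(seq_len(partition$K), function(k) {
      val <- ids[fold == k]
      if (length(val) < 2 || stats::sd(preds[val, tr]) == 0) return(NA_real_)
      stats::cor(preds[val, tr], Y[val, tr])
    }), na.rm = TRUE)
  }, numeric(1))
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("gblup fit: %d lines\n", length(x$line_ids)))
  cat(sprintf("  mu = %.4g, sigma2_g = %.4g, sigma2_e = %.4g (h2 = %.3f)%s\n",
              x$mu, x$sigma2_g, x$sigma2_e, x$h2,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) {
  c(mu = object$mu, sigma2_g = object$sigma2_g, sigma2_e = object$sigma2_e)
}

#' Predict GEBVs for held-out lines
#'
#' `g_hat_new = A[new, train] %*% alpha` under the trained variance
#' components; lines unrelated to the training set shrink to 0 (the
#' prediction is of the centered genetic value; add `mu` for the
#' phenotype scale via `type = "response"`).
#'
#' @param object a `gblup` fit.
#' @param A relationship matrix covering training and new lines.
#' @param newlines character vector of line IDs to predict (default:
#'   all lines of `A` not in training).
#' @param type `"gebv"` (centered genetic value) or `"response"`
#'   (`mu + gebv`).
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.gblup <- function(object, A, newlines = NULL, type = c("gebv", "response"),
                          ...) {
  type <- match.arg(type)
  if (is.null(newlines)) newlines <- setdiff(rownames(A), object$line_ids)
  if (!all(newlines %in% rownames(A))) stop("newlines missing from A")
  g <- drop(unclass(A)[newlines, object$line_ids, drop = FALSE] %*%
              object$alpha[object$line_ids])
  out <- if (type == "response") object$mu + g else g
  stats::setNames(out, newlines)
}

#' Cross-validated genomic prediction accuracy
#'
#' For each fold of the fixed partition, a GBLUP model is fitted on the
#' remaining folds (variance components re-estimated within each
#' training set) and GEBVs predicted for the held-out lines. Accuracy
#' is the average over folds of the Pearson correlation between
#' held-out predictions and observed phenotypes (per-fold accuracy is
#' unbiased under a null trait; pooling predictions across folds before
#' one correlation is available via `pool = TRUE` but carries a
#' negative bias under the null in structured populations). Lines with
#' missing phenotype are excluded from both training and accuracy for
#' that trait.
#'
#' @param y named numeric phenotype vector (missing allowed).
#' @param A relationship matrix covering the lines of `y`.
#' @param partition a [make_partition()] result covering the lines.
#' @param pool pool held-out predictions before one correlation
#'   instead of averaging per-fold correlations (default `FALSE`).
#' @return scalar accuracy in \[-1, 1\], with attribute `"predictions"`
#'   (named vector of held-out GEBVs).
#' @export
cross_validate <- function(y, A, partition, pool = FALSE) {
  stopifnot(inherits(partition, "cv_partition"))
  if (is.null(names(y))) {
    if (length(y) != nrow(A)) stop("unnamed y must match A dimension")
    names(y) <- rownames(A)
  }
  obs <- names(y)[!is.na(y)]
  fold <- partition$fold_of_line
  if (!all(obs %in% names(fold))) stop("phenotyped lines missing from partition")
  preds <- stats::setNames(rep(NA_real_, length(obs)), obs)
  fold_cors <- c()
  for (k in seq_len(partition$K)) {
    val <- obs[fold[obs] == k]
    train <- setdiff(obs, val)
    if (length(val) < 2) next
    fit <- gblup(y[train], A)
    preds[val] <- predict(fit, A, newlines = val)
    if (!pool && stats::sd(preds[val]) > 0)
      fold_cors <- c(fold_cors, stats::cor(preds[val], y[val]))
  }
  used <- obs[!is.na(preds[obs])]
  acc <- if (pool) stats::cor(preds[used], y[used]) else mean(fold_cors)
  attr(acc, "predictions") <- preds
  acc
}

#' Select markers by maximum missing-data rate
#'
#' Per-marker missing rates are computed on the raw (pre-imputation)
#' matrix; downstream analyses then use the imputed scores of exactly
#' the selected subset.
#'
#' @param m the raw `marker_matrix` (with missing cells).
#' @param max_rate maximum per-marker missing fraction.
#' @return character vector of retained marker IDs.
#' @export
filter_by_missing <- function(m, max_rate) {
  rates <- marker_missing_rates(m)
  keep <- names(rates)[rates <= max_rate]
  if (length(keep) == 0)
    stop(sprintf("no markers at max_rate = %g (minimum achievable rate: %g)",
                 max_rate, min(rates)))
  keep
}
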