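#' Per-marker minor allele frequency
#'
#' Allele-1 frequency is `p = mean((score + 1) / 2)` over lines (residual
#' heterozygotes contribute 1/2); MAF = `min(p, 1 - p)`.
#'
#' @param m a `marker_matrix`.
#' @param use_observed if `TRUE`, compute on observed cells only;
#'   otherwise the matrix must be complete (post-imputation).
#' @return named numeric vector of MAFs in \[0, 0.5\].
#' @export
minor_allele_freq <- function(m, use_observed = FALSE) {
  X <- unclass(m)
  if (!use_observed && anyNA(X))
    stop("matrix has missing cells; impute first or set use_observed = TRUE")
  p <- colMeans((X + 1) / 2, na.rm = use_observed)
  pmin(p, 1 - p)
}

#' Binned MAF spectrum
#'
#' Proportion of markers per MAF bin of width `bin_width`: bins
#' (0, w\], (w, 2w\], ..., (0.5 - w, 0.5\]; markers with MAF exactly 0
#' fall in the first bin. Proportions sum to 1.
#'
#' @param mafs numeric vector of MAFs in \[0, 0.5\].
#' @param bin_width bin width (default 0.05).
#' @return named numeric vector of bin proportions.
#' @export
maf_histogram <- function(mafs, bin_width = 0.05) {
  if (length(mafs) == 0) stop("no markers")
  stopifnot(all(mafs >= 0 & mafs <= 0.5 + 1e-12))
  breaks <- seq(0, 0.5, by = bin_width)
  idx <- findInterval(mafs, breaks, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx == 0L] <- 1L  # MAF exactly 0 -> first bin
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  out <- counts / length(mafs)
  names(out) <- sprintf("(%.2f,%.2f]", breaks[-length(breaks)], breaks[-1])
  out
}

#' Realized relationship matrix
#'
#' The marker-based kinship `A = X X' / p` where `X` is the score matrix
#' with columns centered by the marker mean and `p` is the number of
#' markers. The raw, uncentered `X X'` of the score matrix is available
#' with `center = FALSE, scale = FALSE`. Centering plus `1/p` scaling is
#' the default so that matrices built from different marker counts are
#' comparable (required by the Kullback-Leibler and correlation
#' comparisons).
#'
#' @param m a complete `marker_matrix`.
#' @param center center marker columns by their mean (default `TRUE`).
#' @param scale divide by the number of markers (default `TRUE`).
#' @return a `relationship_matrix`: symmetric n x n matrix with line IDs
#'   as dimnames and attribute `n_markers_used`.
#' @export
realized_relationship <- function(m, center = TRUE, scale = TRUE) {
  X <- unclass(m)
  if (anyNA(X)) stop("matrix has missing cells; impute first")
  if (center) X <- sweep(X, 2, colMeans(X))
  A <- tcrossprod(X)
  if (scale) A <- A / ncol(X)
  A <- (A + t(A)) / 2
  attr(A, "n_markers_used") <- ncol(X)
  class(A) <- c("relationship_matrix", "matrix", "array")
  A
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix: %d lines, built from %d markers\n",
              nrow(x), attr(x, "n_markers_used")))
  invisible(x)
}

#' Principal component analysis of a marker matrix
#'
#' Singular value decomposition of the column-centered score matrix.
#' Variance explained by component i is its eigenvalue share
#' `lambda_i / sum(lambda)`; the eigenvalue shares equal those of the
#' realized relationship matrix `X X' / p`.
#'
#' @param m a complete `marker_matrix`.
#' @param k number of components to return (default
#'   `min(n - 1, n_markers)`).
#' @return a `marker_pca` list with `scores` (n x k), `eigenvalues`
#'   (all `min(n-1, p)` eigenvalues, non-increasing) and
#'   `var_explained` (length k, shares of the total).
#' @export
marker_pca <- function(m, k = NULL) {
  X <- unclass(m)
  if (anyNA(X)) stop("matrix has missing cells; impute first")
  if (nrow(X) < 2) stop("need at least 2 lines")
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (is.null(k)) k <- kmax
  if (k > kmax) {
    warning(sprintf("k = %d truncated to %d", k, kmax))
    k <- kmax
  }
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = k, nv = 0)
  ev <- sv$d[seq_len(kmax)]^2
  scores <- sv$u * rep(sv$d[seq_len(k)], each = nrow(X))
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, eigenvalues = ev,
                 var_explained = ev[seq_len(k)] / sum(ev)),
            class = "marker_pca")
}

#' @export
print.marker_pca <- function(x, ...) {
  cat(sprintf("marker_pca: %d lines, %d components kept\n",
              nrow(x$scores), ncol(x$scores)))
  cat("var explained:", paste(sprintf("%.3f", utils::head(x$var_explained, 5)),
                              collapse = " "), "...\n")
  invisible(x)
}

#' Squared correlations between eigenvectors of two PCAs
#'
#' Entry (i, j) is the squared Pearson correlation between score vector
#' i of `p1` and score vector j of `p2` for the same lines in the same
#' order. Squaring makes the comparison invariant to the arbitrary sign
#' of eigenvectors. On matched platforms a diagonal near 1 indicates the
#' two marker sets capture the same diversity pattern in the same order.
#'
#' @param p1,p2 `marker_pca` objects over identical line sets.
#' @param k number of axes to compare.
#' @return k x k matrix of R-squared values.
#' @export
eigenvector_r2 <- function(p1, p2, k = 10) {
  if (nrow(p1$scores) != nrow(p2$scores) ||
      !identical(rownames(p1$scores), rownames(p2$scores)))
    stop("PCAs must be over identical lines in identical order")
  k1 <- min(k, ncol(p1$scores)); k2 <- min(k, ncol(p2$scores))
  stats::cor(p1$scores[, seq_len(k1), drop = FALSE],
             p2$scores[, seq_len(k2), drop = FALSE])^2
}

#' Model-based clustering of lines into subpopulations
#'
#' Fits Gaussian mixture models to the top PCA score dimensions by EM
#' initialized from model-based hierarchical agglomeration (via
#' \pkg{mclust}), over G = 1..`max_groups` components and a family of
#' covariance parameterizations; the (G, model) pair maximizing BIC is
#' returned. Clustering runs on a low-dimensional PCA representation
#' because Gaussian mixtures are degenerate when dimensions far exceed
#' lines.
#'
#' @param scores n x d matrix of PCA scores (or a `marker_pca`).
#' @param max_groups largest number of groups considered (default 10).
#' @param dims number of leading score dimensions used (default
#'   `min(10, d)`).
#' @param model_names mclust covariance parameterizations to consider
#'   (default spherical/diagonal/ellipsoidal, equal and varying volume).
#' @return a `group_assignment` list: `labels` (n integers in 1..G),
#'   `G`, `model`, `bic`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_lines <- function(scores, max_groups = 10, dims = NULL,
                          model_names = c("EII", "VII", "EEI", "VVI",
                                          "EEE", "VVV")) {
  if (inherits(scores, "marker_pca")) scores <- scores$scores
  if (is.null(dims)) dims <- min(10L, ncol(scores))
  S <- scores[, seq_len(min(dims, ncol(scores))), drop = FALSE]
  fit <- mclust::Mclust(S, G = seq_len(max_groups),
                        modelNames = model_names, verbose = FALSE)
  if (is.null(fit)) stop("all mixture candidates failed")
  structure(list(labels = as.integer(fit$classification),
                 G = fit$G, model = fit$modelName, bic = fit$bic),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment: %d groups (model %s, BIC %.1f)\n",
              x$G, x$model, x$bic))
  invisible(x)
}

## Per-locus Weir & Cockerham variance components for haploid allele
## draws; returns the locus-wise numerator a and denominator a + b.
wc_components <- function(x01, labels) {
  groups <- unique(labels)
  r <- length(groups)
  ni <- as.numeric(table(factor(labels, levels = groups)))
  N <- sum(ni)
  nc <- (N - sum(ni^2) / N) / (r - 1)
  pbar_i <- rowsum(x01, factor(labels, levels = groups)) / ni  # r x p
  pbar <- colSums(pbar_i * ni) / N
  ssb <- colSums(ni * sweep(pbar_i, 2, pbar)^2)
  ssw <- colSums((x01 - pbar_i[match(labels, groups), , drop = FALSE])^2)
  msp <- ssb / (r - 1)
  msg <- ssw / (N - r)
  list(num = msp - msg, den = msp + (nc - 1) * msg)
}

#' Weir & Cockerham Fst over subpopulations
#'
#' The variance-components estimator theta of Weir & Cockerham, which is
#' insensitive to differences in subpopulation sizes. Lines are treated
#' as haploid allele draws (appropriate for inbred material); residual
#' heterozygotes contribute 1/2 to each allele count. Per-locus
#' numerator and denominator components are summed over loci and the
#' ratio taken; loci monomorphic overall contribute zero to both sums.
#'
#' @param m a complete `marker_matrix`.
#' @param groups a `group_assignment`, or an integer/factor vector of
#'   group labels (one per line).
#' @return scalar theta estimate.
#' @export
weir_fst <- function(m, groups) {
  if (inherits(groups, "group_assignment")) groups <- groups$labels
  X <- unclass(m)
  if (anyNA(X)) stop("matrix has missing cells; impute first")
  if (length(groups) != nrow(X)) stop("one group label per line required")
  labels <- as.integer(factor(groups))
  ni <- table(labels)
  if (length(ni) < 2) stop("need at least 2 groups")
  if (any(ni < 2)) stop("every group needs at least 2 lines")
  x01 <- (X + 1) / 2
  cmp <- wc_components(x01, labels)
  poly <- colSums(x01) > 0 & colSums(x01) < nrow(X)
  sum(cmp$num[poly]) / sum(cmp$den[poly])
}

#' Overall gene diversity
#'
#' Mean over loci of the unbiased haploid gene diversity
#' `(n / (n - 1)) (1 - sum(p_a^2))`, with allele frequencies from
#' haploid counts (heterozygotes contribute 1/2 to each allele).
#'
#' @param m a complete `marker_matrix`.
#' @return scalar gene diversity.
#' @export
gene_diversity <- function(m) {
  X <- unclass(m)
  if (anyNA(X)) stop("matrix has missing cells; impute first")
  n <- nrow(X)
  p <- colMeans((X + 1) / 2)
  mean((n / (n - 1)) * (1 - (p^2 + (1 - p)^2)))
}

#' Kullback-Leibler divergence between relationship matrices
#'
#' The divergence `D(N(0, S_ref) || N(0, S_sub))` between zero-mean
#' multivariate normals whose covariances are the two relationship
#' matrices (plus a ridge on the diagonal to guarantee
#' non-singularity):
#' `0.5 * (tr(S_sub^-1 S_ref) - n + log det S_sub - log det S_ref)`.
#' It measures the information lost when the subset-based (or
#' candidate-platform) relationship matrix is used to approximate the
#' reference covariance. Computed via Cholesky factorizations, never
#' explicit determinants of raw products.
#'
#' @param A_ref,A_sub `relationship_matrix` objects over identical
#'   lines in identical order.
#' @param ridge diagonal ridge; default `1e-6 * mean(diag)` of each
#'   matrix.
#' @return scalar divergence, non-negative.
#' @export
kl_divergence <- function(A_ref, A_sub, ridge = NULL) {
  if (!isTRUE(all.equal(dim(A_ref), dim(A_sub))))
    stop("matrices must have identical dimensions")
  if (max(abs(A_ref - t(A_ref))) > 1e-8 * (1 + max(abs(A_ref))) ||
      max(abs(A_sub - t(A_sub))) > 1e-8 * (1 + max(abs(A_sub))))
    stop("inputs must be symmetric")
  n <- nrow(A_ref)
  r_ref <- if (is.null(ridge)) 1e-6 * mean(diag(A_ref)) else ridge
  r_sub <- if (is.null(ridge)) 1e-6 * mean(diag(A_sub)) else ridge
  S_ref <- unclass(A_ref) + diag(r_ref, n)
  S_sub <- unclass(A_sub) + diag(r_sub, n)
  L_ref <- chol(S_ref)
  L_sub <- chol(S_sub)
  tr <- sum(backsolve(L_sub, backsolve(L_sub, S_ref, transpose = TRUE))
            [cbind(seq_len(n), seq_len(n))])
  logdet_ref <- 2 * sum(log(diag(L_ref)))
  logdet_sub <- 2 * sum(log(diag(L_sub)))
  d <- 0.5 * (tr - n + logdet_sub - logdet_ref)
  if (d < -1e-8) stop("numerical failure: negative KL divergence ", d)
  max(d, 0)
}

#' Correlation between two relationship matrices
#'
#' Pearson correlation of the vectorized upper triangles, excluding the
#' diagonal by default (diagonal inflation under inbreeding would
#' otherwise dominate).
#'
#' @param A1,A2 symmetric matrices over identical lines in identical
#'   order.
#' @param include_diagonal include the diagonal entries (default
#'   `FALSE`).
#' @return Pearson correlation in \[-1, 1\].
#' @export
matrix_correlation <- function(A1, A2, include_diagonal = FALSE) {
  if (!isTRUE(all.equal(dim(A1), dim(A2))))
    stop("matrices must have identical dimensions")
  ut <- upper.tri(A1, diag = include_diagonal)
  v1 <- A1[ut]; v2 <- A2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in a vectorized triangle")
  stats::cor(v1, v2)
}
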