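#' Subsample markers without replacement
#'
#' Draws a uniform random subset of marker columns (lines unchanged),
#' deterministic given the seed. This is the elementary move of the
#' equal-size subsampling null: reference-platform subsets of the same
#' size as the candidate set.
#'
#' @param m a `marker_matrix`.
#' @param size number of markers to draw (at most `n_markers`).
#' @param seed integer seed.
#' @return a `marker_matrix` with `size` markers.
#' @export
subsample_markers <- function(m, size, seed) {
  if (size > ncol(m)) stop(sprintf("size %d exceeds %d markers", size, ncol(m)))
  if (size < 1) stop("size must be at least 1")
  set.seed(as.integer(seed))
  m[, sort(sample.int(ncol(m), size))]
}

#' Subsampling null distribution of a marker statistic
#'
#' Evaluates `stat_fn` on `B` independent equal-size marker subsamples
#' of the reference matrix. Replicate b uses seed `base_seed + b`, so
#' results are independent of execution order. Failed replicates are
#' excluded and counted; more than 5% failures aborts the run.
#'
#' @param stat_fn function taking a `marker_matrix` and returning a
#'   numeric scalar or vector (constant length).
#' @param ref the reference `marker_matrix` (typically imputed).
#' @param size markers per subsample (the candidate platform's count).
#' @param B number of replicates.
#' @param base_seed integer seed.
#' @return a `bootstrap_distribution`: list with `samples` (B x q
#'   matrix), `B`, `size`, `base_seed`, `n_failed`.
#' @export
bootstrap_distribution <- function(stat_fn, ref, size, B, base_seed = 1) {
  if (B < 1) stop("B must be at least 1")
  samples <- NULL
  failed <- 0L
  for (b in seq_len(B)) {
    sub <- subsample_markers(ref, size, seed = as.integer(base_seed) + b)
    val <- tryCatch(stat_fn(sub), error = function(e) NULL)
    if (is.null(val) || anyNA(val)) { failed <- failed + 1L; next }
    if (is.null(samples))
      samples <- matrix(NA_real_, B, length(val),
                        dimnames = list(NULL, names(val)))
    samples[b, ] <- val
  }
  if (is.null(samples) || failed > 0.05 * B)
    stop(sprintf("%d of %d subsampling replicates failed", failed, B))
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  structure(list(samples = samples, B = B, size = size,
                 base_seed = base_seed, n_failed = failed),
            class = "bootstrap_distribution")
}

#' One-sided empirical p-value against a subsampling null
#'
#' Direction-adaptive: if the observed value lies at or below the null
#' median, `p = #(samples <= observed) / B`, otherwise
#' `p = #(samples >= observed) / B`; ties count as extreme. The p-value
#' is an exact multiple of `1/B` and can be exactly 0 when the observed
#' value lies outside the whole null distribution. No two-sided doubling
#' is applied.
#'
#' @param observed observed candidate-platform value.
#' @param samples numeric vector of null samples (or a
#'   `bootstrap_distribution` with a scalar statistic).
#' @return empirical p-value in \{0, 1/B, ..., 1\}.
#' @export
empirical_pvalue <- function(observed, samples) {
  if (inherits(samples, "bootstrap_distribution")) {
    if (ncol(samples$samples) != 1)
      stop("p-values are defined for scalar statistics")
    samples <- samples$samples[, 1]
  }
  if (length(samples) < 1) stop("need at least one sample")
  if (observed <= stats::median(samples))
    mean(samples <= observed)
  else
    mean(samples >= observed)
}

#' Percentile confidence interval from a subsampling distribution
#'
#' Empirical percentile bounds (linear interpolation) per component of a
#' possibly vector-valued statistic. A candidate value is flagged
#' outside the interval iff below the lower or above the upper bound.
#'
#' @param samples numeric vector, samples x components matrix, or a
#'   `bootstrap_distribution`.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `low`, `high`, `mean` (one row per
#'   component).
#' @export
percentile_ci <- function(samples, level = 0.95) {
  if (inherits(samples, "bootstrap_distribution")) samples <- samples$samples
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  if (nrow(samples) < 40)
    warning("fewer than 40 samples for a percentile interval")
  a <- (1 - level) / 2
  lo <- apply(samples, 2, stats::quantile, probs = a, type = 7, names = FALSE)
  hi <- apply(samples, 2, stats::quantile, probs = 1 - a, type = 7, names = FALSE)
  data.frame(low = lo, high = hi, mean = colMeans(samples),
             row.names = colnames(samples))
}

#' Test a candidate value against a subsampling null
#'
#' Convenience wrapper: builds the null with [bootstrap_distribution()]
#' and returns observed value, null mean, and p-value (scalar
#' statistics) or percentile interval flags (vector statistics).
#'
#' @param stat_fn statistic over a `marker_matrix`.
#' @param ref reference `marker_matrix`.
#' @param cand candidate `marker_matrix` (defines the subsample size
#'   unless `size` is given).
#' @param B replicates (default 1000).
#' @param base_seed integer seed.
#' @param size subsample size (default `ncol(cand)`).
#' @param level level for percentile intervals.
#' @return a `bootstrap_test` list: `statistic` values plus either
#'   `p_value` or `ci` with an `outside` flag per component.
#' @export
bootstrap_test <- function(stat_fn, ref, cand, B = 1000, base_seed = 1,
                           size = NULL, level = 0.95) {
  if (is.null(size)) size <- ncol(cand)
  observed <- stat_fn(cand)
  dist <- bootstrap_distribution(stat_fn, ref, size, B, base_seed)
  if (length(observed) == 1) {
    res <- list(observed = unname(observed),
                null_mean = mean(dist$samples[, 1]),
                p_value = empirical_pvalue(observed, dist$samples[, 1]),
                B = B, size = size, distribution = dist)
  } else {
    ci <- percentile_ci(dist, level)
    res <- list(observed = observed, ci = ci,
                outside = observed < ci$low | observed > ci$high,
                B = B, size = size, distribution = dist)
  }
  class(res) <- "bootstrap_test"
  res
}

#' @export
print.bootstrap_test <- function(x, ...) {
  if (!is.null(x$p_value))
    cat(sprintf("bootstrap_test: observed %.4g vs null mean %.4g (B = %d), p = %.4g\n",
                x$observed, x$null_mean, x$B, x$p_value))
  else
    cat(sprintf("bootstrap_test: %d components, %d outside the %d%% interval (B = %d)\n",
                length(x$observed), sum(x$outside),
                round(100 * (1 - 2 * (1 - 0.975))), x$B))
  invisible(x)
}
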