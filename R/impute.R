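## Per-marker seed derived from (base_seed, marker_id) so imputation is
## reproducible and independent of marker order or scheduling.
marker_seed <- function(base_seed, marker_id) {
  h <- sum(utf8ToInt(marker_id) * seq_along(utf8ToInt(marker_id)))
  as.integer((as.numeric(base_seed) * 31 + h) %% 2147483629) + 1L
}

## Majority vote over per-tree class calls; ties broken toward the
## marker's observed major allele, then toward the smaller score.
majority_vote <- function(votes, major_allele) {
  tab <- table(votes)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  if (length(winners) == 1L) return(winners)
  if (major_allele %in% winners) return(major_allele)
  min(winners)
}

#' Impute missing marker scores with per-marker random forests
#'
#' For each marker with missing calls, a random-forest classifier is
#' trained on the lines observed for that marker, using all other
#' markers of the same platform as predictors (their own missing cells
#' pre-filled with the per-marker mode). The missing calls are then
#' imputed by majority vote over `n_trees` trees. Markers that are
#' monomorphic among observed lines are filled directly with the
#' observed value (the vote is unanimous, no forest is fitted).
#'
#' Observed cells are never altered, and imputed calls only take values
#' observed for that marker. Each marker's forest is seeded from
#' `(base_seed, marker_id)`, so results do not depend on marker order.
#'
#' @param m a `marker_matrix` (one platform; platforms are never pooled).
#' @param n_trees trees per forest (default 100).
#' @param base_seed integer seed.
#' @param mtry predictors tried per split (default `ceiling(sqrt(p))`).
#' @param max_predictors optional cap on the number of predictor markers
#'   per target (a seeded random subset); `NULL` uses all other markers.
#' @param verbose print per-run progress summary.
#' @return a complete `marker_matrix` (zero missing cells).
#' @export
impute_random_forest <- function(m, n_trees = 100, base_seed = 1,
                                 mtry = NULL, max_predictors = NULL,
                                 verbose = FALSE) {
  validate_marker_matrix(m)
  X <- unclass(m)
  miss <- is.na(X)
  if (!any(miss)) return(m)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0))
    stop("marker(s) with zero observed calls: ",
         paste(colnames(X)[n_obs == 0], collapse = ", "),
         " (drop them before imputation)")

  # predictor matrix: per-marker mode prefill
  modes <- apply(X, 2, function(x) {
    tab <- table(x[!is.na(x)])
    as.numeric(names(tab)[which.max(tab)])
  })
  P <- X
  for (j in which(colSums(miss) > 0)) P[miss[, j], j] <- modes[j]

  out <- X
  targets <- which(colSums(miss) > 0)
  t0 <- Sys.time()
  for (j in targets) {
    obs <- !miss[, j]
    vals <- unique(X[obs, j])
    if (length(vals) == 1L) {            # monomorphic fallback
      out[!obs, j] <- vals
      next
    }
    tab <- table(X[obs, j])
    major <- as.numeric(names(tab)[which.max(tab)])
    sd <- marker_seed(base_seed, colnames(X)[j])
    # predictors in canonical (marker-ID) order so results are
    # independent of the column order of the input matrix
    pred_cols <- setdiff(seq_len(ncol(X)), j)
    pred_cols <- pred_cols[order(colnames(X)[pred_cols])]
    if (!is.null(max_predictors) && length(pred_cols) > max_predictors) {
      set.seed(sd)
      pred_cols <- sort(sample(pred_cols, max_predictors))
    }
    fit <- ranger::ranger(x = P[obs, pred_cols, drop = FALSE],
                          y = factor(X[obs, j]),
                          num.trees = n_trees,
                          mtry = if (is.null(mtry)) NULL else mtry,
                          seed = sd, num.threads = 1)
    pr <- stats::predict(fit, P[!obs, pred_cols, drop = FALSE],
                         num.threads = 1, predict.all = TRUE)$predictions
    lev <- as.numeric(fit$forest$levels)
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = sum(!obs))
    calls <- apply(pr, 1, function(v) majority_vote(lev[v], major))
    out[!obs, j] <- calls
  }
  if (verbose)
    message(sprintf("imputed %d markers (%d cells) in %.1f s",
                    length(targets), sum(miss),
                    as.numeric(Sys.time() - t0, units = "secs")))
  res <- marker_matrix(out, platform = attr(m, "platform"))
  if (!is.null(attr(m, "map"))) attr(res, "map") <- attr(m, "map")
  res
}
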