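#' Pairwise marker R-squared matrix
#'
#' Squared Pearson correlation between marker score vectors. With
#' `use_pairwise_complete = TRUE` each pair is evaluated over the lines
#' observed for both markers, and pairs with fewer than `min_overlap`
#' overlapping observations are recorded as missing (the convention used
#' for non-imputed data). Zero-variance markers yield missing R-squared
#' for their pairs. The diagonal is 1.
#'
#' @param m a `marker_matrix` (complete unless pairwise-complete mode).
#' @param use_pairwise_complete evaluate each pair over its jointly
#'   observed lines.
#' @param min_overlap minimum overlapping observations for a
#'   pairwise-complete R-squared (default 30).
#' @return symmetric marker x marker matrix of R-squared values, `NA`
#'   where undefined or under-supported.
#' @export
pairwise_r2 <- function(m, use_pairwise_complete = FALSE, min_overlap = 30) {
  X <- unclass(m)
  if (ncol(X) < 2) stop("need at least 2 markers")
  if (!use_pairwise_complete && anyNA(X))
    stop("matrix has missing cells; impute first or use pairwise-complete mode")
  if (use_pairwise_complete) {
    suppressWarnings(r <- stats::cor(X, use = "pairwise.complete.obs"))
    overlap <- crossprod(!is.na(X))
    r[overlap < min_overlap] <- NA
  } else {
    suppressWarnings(r <- stats::cor(X))
  }
  r2 <- r^2
  diag(r2) <- 1
  dimnames(r2) <- list(colnames(X), colnames(X))
  r2
}

#' Tag-SNP selection by greedy R-squared binning
#'
#' Carlson-style binning: repeatedly take the unassigned marker with the
#' greatest number of unassigned neighbors at R-squared at or above the
#' threshold (ties broken by fewest missing cells, then by marker ID);
#' its bin is itself plus those neighbors, and the bin's tag is the bin
#' member with the fewest missing cells (ties by ID). Bin membership
#' requires association with the bin seed, not with every other member.
#' Missing R-squared counts as below threshold; singletons are their own
#' tags. The number of tags is the number of non-redundant markers.
#'
#' @param r2 symmetric marker x marker R-squared matrix (dimnames =
#'   marker IDs), `NA` allowed.
#' @param threshold redundancy threshold in (0, 1\].
#' @param missing_counts named integer vector of missing-cell counts per
#'   marker (default all zero, e.g. for imputed data).
#' @return a `tag_snp_result` list: `threshold`, `bins` (list of
#'   marker-ID vectors), `tags` (one ID per bin), `n_tags`.
#' @export
tag_snp_select <- function(r2, threshold, missing_counts = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  ids <- colnames(r2)
  p <- ncol(r2)
  if (is.null(missing_counts)) missing_counts <- stats::setNames(integer(p), ids)
  miss <- as.integer(missing_counts[ids])
  adj <- !is.na(r2) & r2 >= threshold
  diag(adj) <- FALSE
  unassigned <- rep(TRUE, p)
  deg <- colSums(adj)
  bins <- list(); tags <- character(0)
  ord_id <- order(ids)  # lexicographic rank for tie-breaking
  rank_id <- integer(p); rank_id[ord_id] <- seq_len(p)
  while (any(unassigned)) {
    cand <- which(unassigned)
    best <- cand[order(-deg[cand], miss[cand], rank_id[cand])][1]
    members <- c(best, cand[adj[cand, best] & cand != best])
    unassigned[members] <- FALSE
    # update neighbor counts among unassigned markers
    if (any(unassigned))
      deg <- deg - rowSums(adj[, members, drop = FALSE])
    # tag: fewest missing cells; ties favor the bin seed, then marker ID
    tag <- members[order(miss[members], members != best, rank_id[members])][1]
    bins[[length(bins) + 1L]] <- ids[sort(members)]
    tags <- c(tags, ids[tag])
  }
  structure(list(threshold = threshold, bins = bins, tags = tags,
                 n_tags = length(tags)),
            class = "tag_snp_result")
}

#' @export
print.tag_snp_result <- function(x, ...) {
  cat(sprintf("tag_snp_result: %d tags (non-redundant markers) at R2 >= %.2f\n",
              x$n_tags, x$threshold))
  invisible(x)
}

#' Count non-redundant markers at several thresholds
#'
#' Convenience wrapper around [pairwise_r2()] and [tag_snp_select()].
#'
#' @param m a `marker_matrix` (typically imputed; the raw pre-imputation
#'   matrix may be supplied via `raw` so tags minimize true missingness).
#' @param thresholds vector of R-squared thresholds.
#' @param raw optional pre-imputation matrix for missing-cell counts.
#' @param use_pairwise_complete,min_overlap passed to [pairwise_r2()].
#' @return named integer vector of tag counts, one per threshold.
#' @export
tag_counts <- function(m, thresholds = c(0.7, 0.8, 0.9), raw = NULL,
                       use_pairwise_complete = FALSE, min_overlap = 30) {
  r2 <- pairwise_r2(m, use_pairwise_complete, min_overlap)
  mc <- if (is.null(raw)) NULL else
    stats::setNames(colSums(is.na(unclass(raw))), colnames(raw))
  out <- vapply(thresholds, function(th)
    tag_snp_select(r2, th, mc)$n_tags, integer(1))
  names(out) <- format(thresholds)
  out
}

#' Variance of pairwise Euclidean distances between markers
#'
#' Euclidean distances are computed between all unordered pairs of
#' marker score vectors (markers as points in line space) and their
#' variance taken (denominator `n_pairs - 1`). A large variance
#' indicates uneven marker distribution across the genome (marker
#' clustering): co-located markers are nearly identical, distant ones
#' are not.
#'
#' @param m a complete `marker_matrix` with at least 2 markers.
#' @return scalar variance, non-negative.
#' @export
distance_variance <- function(m) {
  X <- unclass(m)
  if (anyNA(X)) stop("matrix has missing cells; impute first")
  if (ncol(X) < 2) stop("need at least 2 markers")
  d <- stats::dist(t(X))
  stats::var(as.vector(d))
}
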