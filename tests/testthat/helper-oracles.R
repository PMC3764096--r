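# Shared fixtures and independent oracles used across the suite.

# small marker matrix from a literal score matrix
mm <- function(scores, platform = "test") {
  scores <- as.matrix(scores)
  marker_matrix(scores,
                line_ids = sprintf("L%02d", seq_len(nrow(scores))),
                marker_ids = sprintf("M%02d", seq_len(ncol(scores))),
                platform = platform)
}

# Brute-force Weir & Cockerham variance-components estimator for haploid
# allele draws, written with explicit loops so it shares no code with the
# vectorized implementation. x01: lines x loci allele dosages in [0, 1];
# labels: group per line.
wc_theta_oracle <- function(x01, labels) {
  x01 <- as.matrix(x01)
  groups <- unique(labels)
  r <- length(groups)
  ni <- sapply(groups, function(g) sum(labels == g))
  N <- sum(ni)
  nc <- (N - sum(ni^2) / N) / (r - 1)
  num <- 0; den <- 0
  for (l in seq_len(ncol(x01))) {
    x <- x01[, l]
    if (sum(x) <= 0 || sum(x) >= N) next      # monomorphic overall
    pbar_i <- sapply(groups, function(g) mean(x[labels == g]))
    pbar <- sum(ni * pbar_i) / N
    ssb <- sum(ni * (pbar_i - pbar)^2)
    ssw <- 0
    for (i in seq_along(groups))
      ssw <- ssw + sum((x[labels == groups[i]] - pbar_i[i])^2)
    msp <- ssb / (r - 1)
    msg <- ssw / (N - r)
    num <- num + (msp - msg)
    den <- den + (msp + (nc - 1) * msg)
  }
  num / den
}

# closed-form KL divergence between zero-mean Gaussians, direct formula
kl_gaussian_oracle <- function(S_ref, S_sub) {
  n <- nrow(S_ref)
  0.5 * (sum(diag(solve(S_sub) %*% S_ref)) - n +
           log(det(S_sub)) - log(det(S_ref)))
}

# small, fast simulation preset used where full desk scale is not needed
small_sim <- function(seed, ref_missing = 0, cand_missing = 0,
                      n_ref = 1000, n_cand = 300) {
  sim_config(seed = seed, n_founders = 8, n_families = 8,
             lines_per_family = 15, n_loci_genome = 3000, n_chromosomes = 5,
             reference_platform = platform_model(
               "random_sample", n_markers = n_ref,
               missing_rate_target = ref_missing, name = "reference"),
             candidate_platform = platform_model(
               "panel_ascertained", n_markers = n_cand,
               missing_rate_target = cand_missing, clustering = 25,
               name = "candidate"))
}

# mid-scale preset for bias-detection checks (stronger margins)
mid_sim <- function(seed, ref_missing = 0, cand_missing = 0) {
  sim_config(seed = seed, n_founders = 10, n_families = 10,
             lines_per_family = 18, n_loci_genome = 5000, n_chromosomes = 8,
             reference_platform = platform_model(
               "random_sample", n_markers = 1500,
               missing_rate_target = ref_missing, name = "reference"),
             candidate_platform = platform_model(
               "panel_ascertained", n_markers = 500,
               missing_rate_target = cand_missing, clustering = 25,
               name = "candidate"))
}

# fast per-subsample statistic chain sharing one cross-product: the
# pairwise R2 (for tags) and inter-marker distances both derive from
# crossprod(X), the relationship matrix from the centered tcrossprod
fast_chain_stats <- function(m, A_full, fam) {
  X <- unclass(m)
  p <- ncol(X)
  n <- nrow(X)
  S <- crossprod(X)
  mbar <- colMeans(X)
  Sc <- S - n * tcrossprod(mbar)
  v <- diag(Sc)
  r2 <- (Sc / sqrt(pmax(tcrossprod(v), 1e-300)))^2
  dimnames(r2) <- list(colnames(X), colnames(X))
  diag(r2) <- 1
  d2 <- outer(diag(S), diag(S), "+") - 2 * S
  dvec <- sqrt(pmax(d2[upper.tri(d2)], 0))
  A <- realized_relationship(m)
  c(fst = weir_fst(m, fam),
    kl = kl_divergence(A_full, A),
    a_corr = matrix_correlation(A_full, A),
    tags = tag_snp_select(r2, 0.8)$n_tags,
    dist_var = stats::var(dvec))
}
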