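test_that("minor allele frequencies follow the haploid dosage definition", {
  expect_equal(unname(minor_allele_freq(mm(cbind(c(-1, -1, 1, 1))))), 0.5)
  expect_equal(unname(minor_allele_freq(mm(cbind(c(1, 1, 1, 1))))), 0)
  expect_equal(unname(minor_allele_freq(mm(cbind(c(-1, -1, -1, 1))))), 0.25)
  # heterozygotes count half
  expect_equal(unname(minor_allele_freq(mm(cbind(c(0, 0, 1, -1))))), 0.5)
  expect_error(minor_allele_freq(mm(cbind(c(NA, 1, -1, 1)))), "missing")
  expect_equal(unname(minor_allele_freq(mm(cbind(c(NA, 1, -1, 1))),
                                        use_observed = TRUE)), 1 / 3)
})

test_that("MAF histogram bins are (0,0.05], ..., (0.45,0.5] with zeros in bin 1", {
  expect_equal(unname(maf_histogram(rep(0.5, 4))[10]), 1)
  h <- maf_histogram(c(0.02, 0.07, 0.07, 0.48))
  expect_equal(unname(h[c(1, 2, 10)]), c(0.25, 0.5, 0.25))
  expect_equal(sum(h), 1)
  expect_equal(unname(maf_histogram(c(0, 0.01))[1]), 1)
  expect_error(maf_histogram(numeric(0)), "no markers")
})

test_that("the realized relationship matrix is centered XX'/p", {
  m <- mm(cbind(c(1, -1)))
  A <- realized_relationship(m)
  expect_equal(unclass(A), rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)

  set.seed(5)
  X <- matrix(sample(c(-1, 0, 1), 20 * 50, TRUE), 20, 50)
  X[3, ] <- X[7, ]                       # two identical lines
  m2 <- mm(X)
  A2 <- realized_relationship(m2)
  expect_equal(A2[3, 7], A2[3, 3])
  expect_equal(A2[3, 7], A2[7, 7])
  # independent matrix-product oracle
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(unclass(A2), (Xc %*% t(Xc)) / 50, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_gt(min(eigen(unclass(A2), symmetric = TRUE)$values), -1e-8)
  # raw option
  expect_equal(unclass(realized_relationship(m2, center = FALSE, scale = FALSE)),
               X %*% t(X), ignore_attr = TRUE)
})

test_that("PCA matches a full SVD oracle and degenerates correctly", {
  m <- mm(matrix(rep(c(1, -1, 1, -1, 1), 4), 5, 4))  # identical columns
  p <- marker_pca(m)
  expect_equal(p$var_explained[1], 1)

  set.seed(6)
  X <- matrix(sample(c(-1, 1), 30 * 100, TRUE), 30, 100)
  pm <- marker_pca(mm(X), k = 10)
  # independent oracle: eigenvalues of the centered cross-product matrix
  ev <- eigen(tcrossprod(scale(X, center = TRUE, scale = FALSE)),
              symmetric = TRUE)$values
  expect_equal(pm$var_explained, (ev / sum(ev))[1:10], tolerance = 1e-8)
  expect_warning(marker_pca(mm(X[1:3, 1:5]), k = 10), "truncated")
})

test_that("PCA variance shares equal relationship-matrix eigenvalue shares", {
  set.seed(7)
  X <- matrix(sample(c(-1, 1), 25 * 60, TRUE), 25, 60)
  m <- mm(X)
  p <- marker_pca(m, k = 5)
  ev <- eigen(unclass(realized_relationship(m)), symmetric = TRUE)$values
  expect_equal(p$var_explained, (ev / sum(ev))[1:5], tolerance = 1e-8)
})

test_that("eigenvector R2 is sign-invariant with unit diagonal on self-comparison", {
  set.seed(8)
  X <- matrix(sample(c(-1, 0, 1), 30 * 40, TRUE), 30, 40)
  p1 <- marker_pca(mm(X), k = 5)
  p2 <- p1
  p2$scores <- p2$scores %*% diag(c(-1, 1, -1, 1, -1))  # sign flips
  r2 <- eigenvector_r2(p1, p2, k = 5)
  expect_equal(unname(diag(r2)), rep(1, 5), tolerance = 1e-10)
  expect_error(eigenvector_r2(p1, marker_pca(mm(X[1:10, ]), k = 3), k = 3),
               "identical lines")
})

test_that("mixture clustering recovers planted group structure", {
  set.seed(9)
  blob <- function(n, mu) sweep(matrix(rnorm(n * 3), n, 3), 2, mu, "+")
  two <- rbind(blob(100, c(0, 0, 0)), blob(100, c(10, 10, 10)))
  g2 <- cluster_lines(two, max_groups = 5)
  expect_equal(g2$G, 2)
  expect_equal(length(unique(g2$labels[1:100])), 1)

  one <- blob(200, c(0, 0, 0))
  g1 <- cluster_lines(one, max_groups = 5)
  expect_equal(g1$G, 1)
})

test_that("Weir-Cockerham Fst matches a brute-force variance-components oracle", {
  # two groups fixed for opposite alleles
  fixed <- mm(rbind(matrix(1, 5, 8), matrix(-1, 5, 8)))
  expect_equal(weir_fst(fixed, rep(1:2, each = 5)), 1)

  # identical per-group allele counts: estimator's negative bias at equality
  x <- rbind(matrix(rep(c(1, 1, 1, -1, -1), 4), 5, 4),
             matrix(rep(c(1, 1, 1, -1, -1), 4), 5, 4))
  m_eq <- mm(x)
  labels <- rep(1:2, each = 5)
  theta <- weir_fst(m_eq, labels)
  expect_lte(theta, 0)
  expect_equal(theta, wc_theta_oracle((x + 1) / 2, labels), tolerance = 1e-12)

  # 2 groups x 10 haploid lines, counts (8/2 vs 2/8) at one locus
  x2 <- cbind(c(rep(1, 8), rep(-1, 2), rep(1, 2), rep(-1, 8)))
  m2 <- mm(x2)
  lab2 <- rep(1:2, each = 10)
  expect_equal(weir_fst(m2, lab2),
               wc_theta_oracle((x2 + 1) / 2, lab2), tolerance = 1e-12)

  # random table against the oracle, with residual heterozygotes
  set.seed(10)
  x3 <- matrix(sample(c(-1, -1, 0, 1, 1), 24 * 30, TRUE), 24, 30)
  lab3 <- rep(1:3, each = 8)
  expect_equal(weir_fst(mm(x3), lab3),
               wc_theta_oracle((x3 + 1) / 2, lab3), tolerance = 1e-12)
})

test_that("Fst is invariant to label swaps and group duplication", {
  set.seed(11)
  # two genuinely differentiated groups (frequencies 0.8 vs 0.2)
  x <- rbind(matrix(2 * rbinom(10 * 40, 1, 0.8) - 1, 10, 40),
             matrix(2 * rbinom(10 * 40, 1, 0.2) - 1, 10, 40))
  m <- mm(x)
  lab <- rep(1:2, each = 10)
  f1 <- weir_fst(m, lab)
  expect_equal(weir_fst(m, 3 - lab), f1)
  # duplicating every line leaves the ratio essentially unchanged
  # (size-balance insensitivity; only finite-sample corrections move)
  m2 <- marker_matrix(rbind(x, x),
                      line_ids = sprintf("D%02d", 1:40),
                      marker_ids = colnames(m))
  expect_equal(weir_fst(m2, c(lab, lab)), f1, tolerance = 0.05)
  expect_error(weir_fst(m, rep(1, 20)), "2 groups")
})

test_that("gene diversity follows the unbiased haploid closed form", {
  expect_equal(gene_diversity(mm(matrix(1, 4, 3))), 0)
  x <- cbind(rep(c(1, -1), each = 5))
  expect_equal(gene_diversity(mm(x)), (10 / 9) * 0.5, tolerance = 1e-12)
  # adding a fixed locus lowers the mean
  expect_lt(gene_diversity(mm(cbind(x, 1))), gene_diversity(mm(x)))
})

test_that("KL divergence matches closed forms and the Gaussian oracle", {
  set.seed(12)
  X <- matrix(sample(c(-1, 1), 15 * 40, TRUE), 15, 40)
  A <- realized_relationship(mm(X))
  expect_equal(kl_divergence(A, A), 0, tolerance = 1e-8)

  # scalar case: post-ridge variances 1 and 2
  s_ref <- structure(matrix(1, 1, 1), class = c("relationship_matrix", "matrix", "array"))
  s_sub <- structure(matrix(2, 1, 1), class = c("relationship_matrix", "matrix", "array"))
  expect_equal(kl_divergence(s_ref, s_sub, ridge = 0),
               0.5 * (1 / 2 - 1 + log(2)), tolerance = 1e-10)
  expect_equal(round(kl_divergence(s_ref, s_sub, ridge = 0), 5), 0.09657)

  # 2-D case: Sigma_ref = 2I, Sigma_sub = I
  two_i <- structure(diag(2, 2), class = class(s_ref))
  one_i <- structure(diag(1, 2), class = class(s_ref))
  expect_equal(kl_divergence(two_i, one_i, ridge = 0), 1 - log(2),
               tolerance = 1e-10)

  # random PSD pair vs direct-formula oracle; asymmetry and positivity
  B <- realized_relationship(mm(matrix(sample(c(-1, 1), 15 * 60, TRUE), 15, 60)))
  r <- 1e-6 * mean(diag(A))
  d_ab <- kl_divergence(A, B, ridge = r)
  d_ba <- kl_divergence(B, A, ridge = r)
  expect_equal(d_ab, kl_gaussian_oracle(unclass(A) + diag(r, 15),
                                        unclass(B) + diag(r, 15)),
               tolerance = 1e-6)
  expect_gt(d_ab, 0); expect_gt(d_ba, 0)
  expect_gt(abs(d_ab - d_ba), 1e-6)
  expect_error(kl_divergence(A, structure(matrix(rnorm(225), 15, 15),
                                          class = class(s_ref))),
               "symmetric")
})

test_that("matrix correlation works on off-diagonal triangles", {
  set.seed(13)
  A <- realized_relationship(mm(matrix(sample(c(-1, 1), 10 * 30, TRUE), 10, 30)))
  expect_equal(matrix_correlation(A, A), 1)
  expect_equal(matrix_correlation(A, 3 * A + 2), 1)
  B <- matrix(c(1, .2, .3, .4, .2, 1, .5, .6, .3, .5, 1, .7, .4, .6, .7, 1), 4)
  C <- matrix(c(1, .1, .9, .2, .1, 1, .3, .8, .9, .3, 1, .4, .2, .8, .4, 1), 4)
  expect_equal(matrix_correlation(B, C),
               stats::cor(B[upper.tri(B)], C[upper.tri(C)]))
  expect_error(matrix_correlation(diag(3), diag(3)), "zero variance")
})
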