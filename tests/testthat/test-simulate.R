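test_that("generators are reproducible bit-for-bit from (config, seed)", {
  cfg <- small_sim(5, ref_missing = 0.3, cand_missing = 0.05)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$pop$geno, d2$pop$geno)
  expect_identical(unclass(d1$ref), unclass(d2$ref))
  expect_identical(unclass(d1$cand), unclass(d2$cand))
  expect_identical(d1$phenotypes, d2$phenotypes)
  d3 <- simulate_dataset(small_sim(6, ref_missing = 0.3, cand_missing = 0.05))
  expect_false(identical(unclass(d1$ref), unclass(d3$ref)))
})

test_that("residual heterozygosity after selfing matches the inbreeding expectation", {
  # one large family, 4 selfing generations: expected heterozygosity at
  # loci heterozygous in the F1 is (1/2)^4 = 1/16
  cfg <- sim_config(seed = 3, n_founders = 4, n_families = 1,
                    lines_per_family = 400, selfing_generations = 4,
                    n_loci_genome = 200, n_chromosomes = 4, pool_fst = 0,
                    reference_platform = platform_model("random_sample", 10),
                    candidate_platform = platform_model("panel_ascertained", 10))
  pop <- simulate_population(cfg)
  f1_het <- pop$geno[, apply(pop$geno, 2, function(x) any(x == 0)), drop = FALSE]
  par_diff <- which(colSums(pop$geno == 0) > 0)
  # restrict to loci where the two parents were opposite homozygotes
  fam <- pop$pedigree[1, ]
  het_rate <- mean(pop$geno[, par_diff] == 0)
  # loci in par_diff were F1-heterozygous; binomial SE at ~400 lines x loci
  expect_lt(abs(het_rate - 1 / 16), 0.012)
})

test_that("without selfing all offspring are heterozygous where parents differ", {
  cfg <- sim_config(seed = 9, n_founders = 4, n_families = 1,
                    lines_per_family = 30, selfing_generations = 0,
                    n_loci_genome = 100, n_chromosomes = 2, pool_fst = 0,
                    reference_platform = platform_model("random_sample", 5),
                    candidate_platform = platform_model("panel_ascertained", 5))
  pop <- simulate_population(cfg)
  poly <- apply(pop$geno, 2, function(x) length(unique(x)) > 1)
  # any polymorphic locus in a single F1 family means opposite parents
  expect_true(all(pop$geno[, poly] == 0))
})

test_that("infeasible family configurations error", {
  expect_error(sim_config(n_founders = 4, n_families = 10),
               "n_families")
})

test_that("platform missingness hits its target and can vary per marker", {
  dat <- simulate_dataset(small_sim(11, ref_missing = 0.44, cand_missing = 0.03))
  expect_lt(abs(missing_rate(dat$ref) - 0.44), 0.01)
  expect_lt(abs(missing_rate(dat$cand) - 0.03), 0.01)

  cfg <- small_sim(12)
  pop <- simulate_population(cfg)
  pm <- platform_model("random_sample", 500, missing_rate_target = 0.3,
                       missing_profile = "beta", beta_concentration = 3)
  m <- apply_platform(pop, pm, seed = 1)
  rates <- marker_missing_rates(m)
  expect_lt(abs(mean(rates) - 0.3), 0.03)
  expect_gt(stats::sd(rates), 0.1)   # beta profile disperses per-marker rates
})

test_that("ascertainment with no divergence and a population-sized panel is unbiased", {
  # shared gene pool, no dropout, panel as large as the population:
  # candidate MAF spectrum indistinguishable from a random reference draw
  cfg <- sim_config(seed = 21, n_founders = 8, n_families = 8,
                    lines_per_family = 15, n_loci_genome = 3000,
                    n_chromosomes = 5, shared_ancestry = 1,
                    reference_platform = platform_model(
                      "random_sample", 800, rare_allele_dropout_maf = 0),
                    candidate_platform = platform_model(
                      "panel_ascertained", 800, panel_divergence = 0,
                      panel_size = 120, clustering = 1))
  dat <- simulate_dataset(cfg)
  h_ref <- maf_histogram(minor_allele_freq(dat$ref))
  h_cand <- maf_histogram(minor_allele_freq(dat$cand))
  counts <- rbind(h_ref, h_cand) * 800
  keep <- colSums(counts) > 0
  p <- suppressWarnings(stats::chisq.test(counts[, keep])$p.value)
  expect_gt(p, 0.01)
})

test_that("panel ascertainment distorts the MAF spectrum in the documented direction", {
  hits <- sapply(1:5, function(seed) {
    dat <- simulate_dataset(mid_sim(seed + 100))
    maf_pop <- {
      g <- dat$pop$geno
      fr <- colMeans((g + 1) / 2)
      pmin(fr, 1 - fr)
    }
    base_cand <- sub("_c[0-9]+$", "", colnames(dat$cand))
    c(rare = mean(maf_pop[base_cand] < 0.2) > mean(maf_pop[colnames(dat$ref)] < 0.2),
      common = mean(maf_pop[base_cand] > 0.4) < mean(maf_pop[colnames(dat$ref)] > 0.4))
  })
  expect_gte(mean(hits["rare", ]), 4 / 5)
  expect_gte(mean(hits["common", ]), 4 / 5)
})

test_that("marker clustering raises the variance of inter-marker distances", {
  diffs <- sapply(1:20, function(seed) {
    cfg <- small_sim(seed + 300)
    pop <- simulate_population(cfg)
    m_cl <- apply_platform(pop, platform_model("panel_ascertained", 300,
                                               clustering = 25), seed = 1)
    m_un <- apply_platform(pop, platform_model("panel_ascertained", 300,
                                               clustering = 1), seed = 1)
    distance_variance(m_cl) - distance_variance(m_un)
  })
  expect_gt(mean(diffs), 0)           # Monte-Carlo aggregate over 20 seeds
  expect_gte(mean(diffs > 0), 0.8)
})

test_that("full-sib families form kinship clusters", {
  for (seed in c(1, 2, 3)) {
    dat <- simulate_dataset(small_sim(seed + 500))
    A <- realized_relationship(marker_matrix(dat$pop$geno, platform = "true"))
    fam <- dat$pop$pedigree$family
    same <- outer(fam, fam, "==")
    diag(same) <- NA
    expect_gt(mean(A[which(same)]), mean(A[which(!same)]))
  }
})

test_that("candidate Fst exceeds equal-size reference subsets under divergence", {
  hits <- sapply(1:20, function(seed) {
    dat <- simulate_dataset(small_sim(seed + 700))
    fam <- dat$pop$pedigree$family
    fst_cand <- weir_fst(dat$cand, fam)
    fst_ref <- mean(sapply(1:5, function(s) {
      weir_fst(subsample_markers(dat$ref, ncol(dat$cand), seed = s), fam)
    }))
    fst_cand > fst_ref
  })
  expect_gte(mean(hits), 0.95)
})

test_that("phenotype simulation respects heritability", {
  cfg <- small_sim(31)
  pop <- simulate_population(cfg)
  tr <- data.frame(name = c("perfect", "none"), h2 = c(1, 0), n_qtl = 50)
  ph <- simulate_phenotypes(pop$geno, tr, seed = 1)
  expect_equal(stats::cor(ph$y[, "perfect"], ph$truth$perfect$g), 1)

  # h2 = 0: phenotype independent of the genetic value
  cors <- sapply(1:100, function(s) {
    p <- simulate_phenotypes(pop$geno, data.frame(name = "t", h2 = 0, n_qtl = 50),
                             seed = s)
    stats::cor(p$y[, 1], p$truth$t$g)
  })
  expect_lt(abs(mean(cors)), 0.05)

  # h2 = 0.5 at n = 1000 lines: realized variance ratio recovers 0.5
  cfg2 <- sim_config(seed = 32, n_founders = 8, n_families = 8,
                     lines_per_family = 125, n_loci_genome = 600,
                     n_chromosomes = 3,
                     reference_platform = platform_model("random_sample", 50),
                     candidate_platform = platform_model("panel_ascertained", 50))
  pop2 <- simulate_population(cfg2)
  ph2 <- simulate_phenotypes(pop2$geno,
                             data.frame(name = "t", h2 = 0.5, n_qtl = 100),
                             seed = 7)
  ratio <- stats::var(ph2$truth$t$g) / stats::var(ph2$y[, 1])
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("platform errors are informative", {
  cfg <- small_sim(41)
  pop <- simulate_population(cfg)
  expect_error(apply_platform(pop, platform_model("random_sample", 999999),
                              seed = 1),
               "eligible loci")
})
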