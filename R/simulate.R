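#' Platform model for simulated genotyping
#'
#' Describes how one genotyping platform samples markers from the
#' simulated genome. `"random_sample"` draws markers uniformly (or per
#' the clustering parameter) from loci polymorphic in the target
#' population with MAF at or above `rare_allele_dropout_maf`, emulating a
#' sequencing platform whose pipeline discards very rare variants as
#' putative errors. `"panel_ascertained"` first simulates a small
#' discovery panel drawn from a gene pool whose per-locus allele
#' frequencies are a divergence-weighted mixture of the target founder
#' frequencies and an independent draw from the same spectrum; only loci
#' polymorphic within that panel are eligible, emulating array design on
#' an independent screening panel.
#'
#' @param mode `"random_sample"` or `"panel_ascertained"`.
#' @param n_markers number of markers to draw.
#' @param missing_rate_target fraction of cells masked missing,
#'   missing-completely-at-random, in \[0, 1).
#' @param panel_size discovery-panel size (ascertained mode).
#' @param panel_divergence divergence between the target gene pool and
#'   the discovery-panel gene pool, in \[0, 1\]: the panel's per-locus
#'   allele frequency is `(1 - F) * p0 + F * u` with `u` an independent
#'   draw from the founder frequency spectrum, so 0 = same pool and
#'   1 = unrelated pool with the same spectrum.
#' @param clustering spatial concentration of marker positions: 1 =
#'   uniform across the genome, > 1 = relative sampling weight of loci
#'   inside hotspot windows (restriction-site non-uniformity analog).
#' @param hotspot_width width (Morgan) of each hotspot window.
#' @param hotspots_per_chromosome number of hotspot windows per
#'   chromosome.
#' @param rare_allele_dropout_maf MAF threshold below which
#'   random-sample variants are discarded.
#' @param missing_profile `"constant"` for one missing rate shared by
#'   all markers, `"beta"` for per-marker rates drawn from a beta
#'   distribution with mean `missing_rate_target`.
#' @param beta_concentration concentration of the per-marker
#'   missing-rate beta distribution (larger = less dispersed).
#' @param name platform label attached to the output matrix.
#' @return a `platform_model` list.
#' @export
platform_model <- function(mode = c("random_sample", "panel_ascertained"),
                           n_markers, missing_rate_target = 0,
                           panel_size = 13, panel_divergence = 0.9,
                           clustering = 1, rare_allele_dropout_maf = 0.12,
                           missing_profile = c("constant", "beta"),
                           beta_concentration = 4,
                           hotspot_width = 0.005, hotspots_per_chromosome = 3,
                           name = NULL) {
  mode <- match.arg(mode)
  missing_profile <- match.arg(missing_profile)
  stopifnot(n_markers >= 1, missing_rate_target >= 0, missing_rate_target < 1,
            clustering >= 1, panel_size >= 2,
            panel_divergence >= 0, panel_divergence <= 1)
  if (is.null(name))
    name <- if (mode == "random_sample") "reference" else "candidate"
  structure(list(mode = mode, n_markers = n_markers,
                 missing_rate_target = missing_rate_target,
                 panel_size = panel_size, panel_divergence = panel_divergence,
                 clustering = clustering,
                 rare_allele_dropout_maf = rare_allele_dropout_maf,
                 missing_profile = missing_profile,
                 beta_concentration = beta_concentration,
                 hotspot_width = hotspot_width,
                 hotspots_per_chromosome = hotspots_per_chromosome,
                 name = name),
            class = "platform_model")
}

#' Simulation configuration for an inbred breeding population
#'
#' Defaults describe the desk-scale study population: 360 F5-derived
#' lines in 12 full-sib families crossed from a pool of 12 recurrent
#' inbred founders (families share parents, as in an elite breeding
#' program), 12,000 genome loci on 10 chromosomes, a reference platform of 4,000 markers with
#' 43.9% missing data and a candidate platform of 1,500 markers
#' ascertained on a 13-line discovery panel with 3.1% missing data, and
#' four traits with line-mean heritabilities 0.29, 0.73, 0.77 and 0.24.
#'
#' @param n_founders number of inbred founder lines.
#' @param n_families number of biparental families: distinct founder
#'   pairs, possibly sharing founders (at most `choose(n_founders, 2)`).
#' @param n_ancestral_pools number of ancestral gene pools the founders
#'   descend from (market classes / breeding origins).
#' @param pool_fst Balding-Nichols differentiation among ancestral
#'   pools, in \[0, 1).
#' @param ld_decay distance scale (Morgan) of linkage disequilibrium
#'   within founder haplotypes: founder alleles follow a Gaussian-copula
#'   AR(1) along each chromosome with latent correlation
#'   `exp(-d / ld_decay)` at map distance `d`.
#' @param shared_ancestry fraction of loci whose polymorphism predates
#'   the split of the ancestral pools (old alleles: frequencies drifted
#'   apart among target pools, segregating in the discovery panel's
#'   pool); the rest are young variants that arose inside the breeding
#'   program (one shared frequency across target pools, absent from the
#'   panel's pool).
#' @param lines_per_family integer vector (recycled to `n_families`) of
#'   lines derived per family.
#' @param selfing_generations selfing generations after the F1 (4 for
#'   F5-derived material).
#' @param n_loci_genome number of biallelic loci simulated.
#' @param n_chromosomes number of chromosomes.
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (chromosome length in Morgans).
#' @param founder_maf_distribution `"ushaped"` (allele frequency
#'   Beta(0.4, 0.4) truncated to \[0.02, 0.98\], the rare-heavy spectrum
#'   typical of diverse germplasm; default) or `"uniform"` (MAF uniform
#'   on \[0.05, 0.5\]).
#' @param reference_platform,candidate_platform [platform_model()]s.
#' @param traits data.frame with columns `name`, `h2`, `n_qtl`.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 12, n_families = 12,
                       n_ancestral_pools = 2, pool_fst = 0.4,
                       shared_ancestry = 0.5, ld_decay = 0.1,
                       lines_per_family = 30, selfing_generations = 4,
                       n_loci_genome = 12000, n_chromosomes = 10,
                       recomb_rate = 1.5,
                       founder_maf_distribution = c("ushaped", "uniform"),
                       reference_platform = platform_model(
                         "random_sample", n_markers = 4000,
                         missing_rate_target = 0.439, clustering = 1,
                         rare_allele_dropout_maf = 0.12, name = "reference"),
                       candidate_platform = platform_model(
                         "panel_ascertained", n_markers = 1500,
                         missing_rate_target = 0.031, panel_size = 13,
                         panel_divergence = 0.9, clustering = 25,
                         name = "candidate"),
                       traits = data.frame(
                         name = c("yield", "heading_date", "height", "phs"),
                         h2 = c(0.29, 0.73, 0.77, 0.24),
                         n_qtl = 100),
                       seed = 1L) {
  founder_maf_distribution <- match.arg(founder_maf_distribution)
  lines_per_family <- rep_len(lines_per_family, n_families)
  stopifnot(n_founders >= 4, n_families >= 1,
            n_families <= choose(n_founders, 2),
            n_ancestral_pools >= 1, pool_fst >= 0, pool_fst < 1,
            shared_ancestry > 0, shared_ancestry <= 1, ld_decay > 0,
            selfing_generations >= 0, n_loci_genome >= 1,
            all(traits$h2 >= 0 & traits$h2 <= 1),
            max(reference_platform$n_markers,
                candidate_platform$n_markers) <= n_loci_genome)
  structure(list(n_founders = n_founders, n_families = n_families,
                 n_ancestral_pools = n_ancestral_pools, pool_fst = pool_fst,
                 shared_ancestry = shared_ancestry, ld_decay = ld_decay,
                 lines_per_family = lines_per_family,
                 selfing_generations = selfing_generations,
                 n_loci_genome = n_loci_genome,
                 n_chromosomes = n_chromosomes, recomb_rate = recomb_rate,
                 founder_maf_distribution = founder_maf_distribution,
                 reference_platform = reference_platform,
                 candidate_platform = candidate_platform,
                 traits = traits, seed = as.integer(seed)),
            class = "sim_config")
}

## One gamete from a heterozygous plant: crossovers Poisson(L) per
## chromosome, positions uniform, random starting haplotype.
meiosis_gamete <- function(h1, h2, map_split) {
  gam <- h1
  for (chr in map_split) {
    idx <- chr$idx
    n_xo <- stats::rpois(1, chr$len)
    start <- stats::rbinom(1, 1, 0.5)
    if (n_xo == 0) {
      if (start == 1L) gam[idx] <- h2[idx]
    } else {
      xo <- sort(stats::runif(n_xo, 0, chr$len))
      seg <- findInterval(chr$pos, xo)
      take2 <- (start + seg) %% 2 == 1
      gam[idx][take2] <- h2[idx][take2]
    }
  }
  gam
}

#' Simulate an inbred breeding population
#'
#' Founders are inbred lines with allele frequencies drawn from the
#' configured MAF distribution. Each family is a biparental cross of a
#' distinct founder pair; the F1 is advanced by single-seed descent for
#' `selfing_generations` generations with recombination, so residual
#' heterozygosity at loci heterozygous in the F1 is (1/2)^generations in
#' expectation.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` (lines x loci score matrix in \{-1,0,1\}),
#'   `map` (data.frame marker/chrom/pos, positions in Morgans),
#'   `pedigree` (line, family, parents), and `founder_freq` (per-locus
#'   allele-1 frequency used to draw founders).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci_genome
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), L))
  pos <- stats::runif(L, 0, cfg$recomb_rate)
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  map <- data.frame(marker = sprintf("L%05d", seq_len(L)),
                    chrom = chrom, pos = pos)
  map_split <- lapply(split(seq_len(L), chrom), function(idx)
    list(idx = idx, pos = pos[idx], len = cfg$recomb_rate))

  p_base <- switch(cfg$founder_maf_distribution,
    uniform = {
      maf <- stats::runif(L, 0.05, 0.5)
      ifelse(stats::runif(L) < 0.5, maf, 1 - maf)
    },
    ushaped = pmin(pmax(stats::rbeta(L, 0.4, 0.4), 0.02), 0.98))

  # Allele age: old loci predate the split of the target's ancestral
  # pools from each other and from the discovery panel's gene pool, so
  # their frequencies have drifted apart among pools (and only they
  # segregate in the panel's pool). Young loci arose within the breeding
  # program after the splits: they circulate freely across the target
  # pools (one shared frequency, no drift) and are absent from the
  # panel's gene pool.
  K <- cfg$n_ancestral_pools
  old <- stats::runif(L) < cfg$shared_ancestry
  pool_freq <- matrix(p_base, L, K)
  if (K > 1 && cfg$pool_fst > 0) {
    Fp <- cfg$pool_fst
    a <- p_base * (1 - Fp) / Fp
    b <- (1 - p_base) * (1 - Fp) / Fp
    pool_freq[old, ] <- matrix(
      stats::rbeta(sum(old) * K, rep(pmax(a[old], 1e-8), K),
                   rep(pmax(b[old], 1e-8), K)),
      sum(old), K, byrow = FALSE)
  }
  founder_pool <- rep_len(seq_len(K), cfg$n_founders)
  # Founder haplotypes carry LD: a Gaussian-copula AR(1) latent process
  # along each chromosome (correlation exp(-d/ld_decay)) thresholded at
  # the pool frequency, so marginals stay Balding-Nichols while linked
  # loci are associated population-wide.
  chrom_idx <- split(seq_len(L), chrom)
  founders <- matrix(0L, cfg$n_founders, L)
  for (i in seq_len(cfg$n_founders)) {
    u <- numeric(L)
    for (idx in chrom_idx) {
      m <- length(idx)
      rho <- exp(-diff(pos[idx]) / cfg$ld_decay)
      e <- stats::rnorm(m)
      ui <- numeric(m)
      ui[1] <- e[1]
      for (l in seq_len(m - 1L))
        ui[l + 1L] <- rho[l] * ui[l] + sqrt(1 - rho[l]^2) * e[l + 1L]
      u[idx] <- ui
    }
    founders[i, ] <- as.integer(stats::pnorm(u) < pool_freq[, founder_pool[i]])
  }

  # families are distinct founder PAIRS; founders may recur across
  # families (recurrent elite parents), giving half-sib connections.
  # Crosses stay within an ancestral pool (elite x elite adapted
  # material) unless a pool has too few founders to supply them.
  all_pairs <- t(utils::combn(cfg$n_founders, 2))
  same_pool <- founder_pool[all_pairs[, 1]] == founder_pool[all_pairs[, 2]]
  pool_pairs <- all_pairs[same_pool, , drop = FALSE]
  pair_idx <- if (nrow(pool_pairs) >= cfg$n_families)
    pool_pairs[sample.int(nrow(pool_pairs), cfg$n_families), , drop = FALSE]
  else
    all_pairs[sample.int(nrow(all_pairs), cfg$n_families), , drop = FALSE]
  n_lines <- sum(cfg$lines_per_family)
  geno <- matrix(0L, n_lines, L)
  ped <- data.frame(line = sprintf("line%04d", seq_len(n_lines)),
                    family = rep(seq_len(cfg$n_families), cfg$lines_per_family),
                    parent1 = rep(pair_idx[, 1], cfg$lines_per_family),
                    parent2 = rep(pair_idx[, 2], cfg$lines_per_family))
  row <- 0L
  for (f in seq_len(cfg$n_families)) {
    f1_h1 <- founders[pair_idx[f, 1], ]
    f1_h2 <- founders[pair_idx[f, 2], ]
    for (k in seq_len(cfg$lines_per_family[f])) {
      h1 <- f1_h1; h2 <- f1_h2
      for (g in seq_len(cfg$selfing_generations)) {
        g1 <- meiosis_gamete(h1, h2, map_split)
        g2 <- meiosis_gamete(h1, h2, map_split)
        h1 <- g1; h2 <- g2
      }
      row <- row + 1L
      geno[row, ] <- h1 + h2 - 1L
    }
  }
  dimnames(geno) <- list(ped$line, map$marker)
  list(geno = geno, map = map, pedigree = ped, founder_freq = p_base,
       pool_freq = pool_freq, founder_pool = founder_pool,
       panel_pool_freq = ifelse(old, p_base, 0))
}

#' Genotype a simulated population on a platform
#'
#' Applies a [platform_model()] to the true genotypes: selects eligible
#' loci per the ascertainment mode, samples marker positions (optionally
#' concentrated in hotspot windows), and masks cells missing at random.
#' Eligible loci are always polymorphic in the target population.
#'
#' @param pop result of [simulate_population()].
#' @param pm a [platform_model()].
#' @param seed integer seed controlling panel simulation, marker
#'   sampling, and missingness masking.
#' @return a `marker_matrix` with a `map` attribute for the selected
#'   markers.
#' @export
apply_platform <- function(pop, pm, seed) {
  stopifnot(inherits(pm, "platform_model"))
  set.seed(as.integer(seed))
  geno <- pop$geno
  n <- nrow(geno); L <- ncol(geno)
  freq <- colMeans((geno + 1) / 2)
  maf <- pmin(freq, 1 - freq)

  if (pm$mode == "random_sample") {
    eligible <- which(maf > 0 & maf >= pm$rare_allele_dropout_maf)
  } else {
    # Discovery-panel gene pool: per-locus allele frequency is a mixture
    # of the target founder frequency and an independent draw from the
    # same frequency spectrum (a permutation of the founder frequencies),
    # so panel_divergence = 0 reproduces the target gene pool and
    # panel_divergence = 1 an unrelated pool with the same spectrum.
    F <- pm$panel_divergence
    # The panel's gene pool carries only the old (pre-split) alleles, at
    # frequencies mixing the ancestral base frequency with an
    # independent draw from the same spectrum (divergent drift).
    p0 <- pop$panel_pool_freq
    q <- numeric(L)
    seg <- p0 > 0
    q[seg] <- (1 - F) * p0[seg] + F * sample(p0[seg])
    panel <- matrix(stats::rbinom(pm$panel_size * L, 1, rep(q, each = pm$panel_size)),
                    nrow = pm$panel_size)
    panel_count <- colSums(panel)
    eligible <- which(panel_count > 0 & panel_count < pm$panel_size & maf > 0)
  }
  if (length(eligible) < pm$n_markers)
    stop(sprintf("platform '%s': only %d eligible loci for %d requested markers",
                 pm$name, length(eligible), pm$n_markers))

  w <- rep(1, length(eligible))
  if (pm$clustering > 1) {
    chrs <- unique(pop$map$chrom)
    hot <- rep(FALSE, L)
    for (ch in chrs) {
      idx <- which(pop$map$chrom == ch)
      len <- max(pop$map$pos[idx])
      centers <- stats::runif(pm$hotspots_per_chromosome, 0, len)
      for (ce in centers)
        hot[idx] <- hot[idx] | abs(pop$map$pos[idx] - ce) <= pm$hotspot_width / 2
    }
    w <- ifelse(hot[eligible], pm$clustering, 1)
  }
  if (pm$clustering > 1) {
    # Clustered platforms assay hotspot loci repeatedly (multiple array
    # clones of the same restriction fragment), so draws are with
    # replacement; repeat draws become distinct markers with identical
    # scores, suffixed by a clone number.
    sel <- sort(sample(eligible, pm$n_markers, prob = w, replace = TRUE))
  } else {
    sel <- sort(sample(eligible, pm$n_markers, prob = w))
  }
  scores <- geno[, sel, drop = FALSE]
  dup <- stats::ave(seq_along(sel), sel, FUN = seq_along)
  colnames(scores) <- ifelse(dup == 1L, colnames(geno)[sel],
                             paste0(colnames(geno)[sel], "_c", dup))

  if (pm$missing_rate_target > 0) {
    rate <- if (pm$missing_profile == "constant") {
      rep(pm$missing_rate_target, pm$n_markers)
    } else {
      k <- pm$beta_concentration
      stats::rbeta(pm$n_markers, k * pm$missing_rate_target,
                   k * (1 - pm$missing_rate_target))
    }
    mask <- matrix(stats::runif(n * pm$n_markers) <
                     rep(rate, each = n), n, pm$n_markers)
    scores[mask] <- NA
  }
  m <- marker_matrix(scores, platform = pm$name)
  attr(m, "map") <- pop$map[sel, ]
  m
}

#' Simulate phenotypes under an additive genetic model
#'
#' Per trait, `n_qtl` loci are sampled from the genome, additive effects
#' are drawn from a standard normal, genetic values are `g = X_qtl beta`,
#' and environmental noise is scaled so that
#' `var(e) = var(g) (1 - h2) / h2`. With `h2 = 1` the phenotype equals
#' the genetic value; with `h2 = 0` it is pure noise with the variance
#' of `g`.
#'
#' @param geno lines x loci true score matrix.
#' @param traits data.frame with columns `name`, `h2`, `n_qtl`.
#' @param seed integer seed.
#' @return list with `y` (lines x traits phenotype matrix) and `truth`
#'   (per-trait QTL indices, effects and genetic values).
#' @export
simulate_phenotypes <- function(geno, traits, seed) {
  set.seed(as.integer(seed))
  n <- nrow(geno)
  y <- matrix(NA_real_, n, nrow(traits),
              dimnames = list(rownames(geno), traits$name))
  truth <- vector("list", nrow(traits)); names(truth) <- traits$name
  for (t in seq_len(nrow(traits))) {
    h2 <- traits$h2[t]
    qtl <- sample.int(ncol(geno), traits$n_qtl[t])
    beta <- stats::rnorm(traits$n_qtl[t])
    g <- drop(geno[, qtl, drop = FALSE] %*% beta)
    vg <- stats::var(g)
    if (vg == 0) vg <- 1
    if (h2 == 0) {
      e <- stats::rnorm(n, sd = sqrt(vg))
      y[, t] <- e
    } else if (h2 == 1) {
      y[, t] <- g
    } else {
      e <- stats::rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
      y[, t] <- g + e
    }
    truth[[t]] <- list(qtl = qtl, beta = beta, g = g)
  }
  list(y = y, truth = truth)
}

#' Simulate a complete two-platform dataset
#'
#' Runs [simulate_population()], genotypes the population on the
#' reference and candidate platforms, and simulates phenotypes. Platform
#' and phenotype seeds are derived deterministically from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `pop`, `ref`, `cand`, `phenotypes` (matrix),
#'   `truth`, and `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  pop <- simulate_population(cfg)
  s <- cfg$seed
  ref <- apply_platform(pop, cfg$reference_platform, seed = (s * 7 + 1) %% 2147483647)
  cand <- apply_platform(pop, cfg$candidate_platform, seed = (s * 7 + 2) %% 2147483647)
  ph <- simulate_phenotypes(pop$geno, cfg$traits, seed = (s * 7 + 3) %% 2147483647)
  list(pop = pop, ref = ref, cand = cand,
       phenotypes = ph$y, truth = ph$truth, cfg = cfg)
}
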