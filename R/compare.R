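#' Compare a candidate marker platform against a reference platform
#'
#' Runs the full ascertainment-bias comparison between two marker
#' matrices genotyped on the same lines: per-platform random-forest
#' imputation; all-marker PCA per platform and between-platform
#' eigenvector R-squared; an equal-size marker-subsampling null over the
#' diversity statistics (number of mixture-model groups, variance
#' explained by the first two PCs, Weir-Cockerham Fst over the inferred
#' groups, Kullback-Leibler divergence from the all-reference
#' relationship matrix, relationship-matrix correlation, gene
#' diversity); percentile intervals for the MAF spectrum and the
#' per-axis PCA variances; tag-SNP counts per R-squared threshold with
#' subsampling p-values; the variance of pairwise marker distances; and
#' GBLUP cross-validated accuracy per trait (all markers and tag
#' markers, each against its own reference null), all folds sharing one
#' fixed partition.
#'
#' Each null replicate re-runs the full statistic chain on a fresh
#' subsample (subsample, then cluster, then Fst on the resulting
#' groups); clustering is never reused across replicates. P-values are
#' one-sided, direction-adaptive and exact multiples of 1/B.
#'
#' @param ref reference-platform `marker_matrix` (e.g. GBS-like: many
#'   markers, high missingness).
#' @param cand candidate-platform `marker_matrix` (e.g. array-like:
#'   fewer markers, ascertained on a panel).
#' @param phenotypes optional lines x traits matrix of BLUEs; `NULL`
#'   skips the prediction stage.
#' @param B subsampling replicates for the diversity/redundancy nulls.
#' @param B_gs replicates for the prediction nulls (default `B`).
#' @param seed integer seed governing imputation, subsampling and the
#'   cross-validation partition.
#' @param thresholds tag-SNP R-squared thresholds.
#' @param gs_tag_threshold threshold used for the tag-marker prediction
#'   stage (default 0.8).
#' @param K cross-validation folds.
#' @param n_trees trees per imputation forest.
#' @param max_predictors optional cap on imputation predictors (passed
#'   to [impute_random_forest()]).
#' @param pca_axes axes reported for eigenvector R-squared and per-axis
#'   variance intervals.
#' @param cluster_max_groups,cluster_dims,cluster_models passed to
#'   [cluster_lines()].
#' @param stages character subset of
#'   `c("diversity", "redundancy", "prediction")`.
#' @param verbose print stage progress.
#' @return a `platform_comparison` object; see [print.platform_comparison()].
#' @export
compare_platforms <- function(ref, cand, phenotypes = NULL,
                              B = 1000, B_gs = B, seed = 1,
                              thresholds = c(0.7, 0.8, 0.9),
                              gs_tag_threshold = 0.8,
                              K = 10, n_trees = 100, max_predictors = NULL,
                              pca_axes = 10,
                              cluster_max_groups = 10, cluster_dims = 10,
                              cluster_models = c("EII", "VII", "EEI", "VVI",
                                                 "EEE", "VVV"),
                              stages = c("diversity", "redundancy",
                                         "prediction"),
                              verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  al <- align_lines(ref, cand, phenotypes)
  ref <- al$ref; cand <- al$cand; phenotypes <- al$phenotypes
  n <- nrow(ref)
  size <- ncol(cand)
  if (size > ncol(ref))
    stop("candidate has more markers than the reference; the equal-size null needs size <= reference markers")

  miss <- c(reference = missing_rate(ref), candidate = missing_rate(cand))
  say("imputing (%d + %d markers)", ncol(ref), ncol(cand))
  ref_imp <- impute_random_forest(ref, n_trees, base_seed = seed,
                                  max_predictors = max_predictors)
  cand_imp <- impute_random_forest(cand, n_trees, base_seed = seed + 1L,
                                   max_predictors = max_predictors)

  out <- list(missing_rates = miss, n_lines = n,
              n_markers = c(reference = ncol(ref), candidate = ncol(cand)),
              B = B, B_gs = B_gs, seed = seed, subsample_size = size,
              imputed = list(reference = ref_imp, candidate = cand_imp),
              raw = list(reference = ref, candidate = cand))

  A_ref_full <- realized_relationship(ref_imp)
  pca_axes <- min(pca_axes, n - 1, size)

  chain <- function(msub) {
    pc <- marker_pca(msub, k = max(pca_axes, cluster_dims))
    grp <- tryCatch(cluster_lines(pc$scores, cluster_max_groups,
                                  dims = cluster_dims,
                                  model_names = cluster_models),
                    error = function(e) NULL)
    fst <- NA_real_; ngroups <- NA_real_
    if (!is.null(grp)) {
      ngroups <- grp$G
      big <- which(tabulate(grp$labels) >= 2)
      keep <- grp$labels %in% big
      if (length(big) >= 2)
        fst <- tryCatch(weir_fst(msub[keep, ], grp$labels[keep]),
                        error = function(e) NA_real_)
    }
    A <- realized_relationship(msub)
    mafs <- minor_allele_freq(msub)
    c(n_groups = ngroups,
      r2_pc1 = pc$var_explained[1], r2_pc2 = pc$var_explained[2],
      fst = fst,
      kl = kl_divergence(A_ref_full, A),
      a_corr = matrix_correlation(A_ref_full, A),
      gene_diversity = gene_diversity(msub),
      dist_var = distance_variance(msub),
      stats::setNames(if ("redundancy" %in% stages)
                        tag_counts(msub, thresholds) else
                        rep(NA_real_, length(thresholds)),
                      paste0("tags_", format(thresholds))),
      stats::setNames(maf_histogram(mafs), paste0("maf_bin", 1:10)),
      stats::setNames(pc$var_explained[seq_len(pca_axes)],
                      paste0("pc_var", seq_len(pca_axes))))
  }

  if ("diversity" %in% stages || "redundancy" %in% stages) {
    say("observed candidate statistic chain")
    observed <- chain(cand_imp)
    say("subsampling null: B = %d chains of %d markers", B, size)
    samples <- matrix(NA_real_, B, length(observed),
                      dimnames = list(NULL, names(observed)))
    for (b in seq_len(B)) {
      sub <- subsample_markers(ref_imp, size, seed = seed + 1000L + b)
      samples[b, ] <- tryCatch(chain(sub), error = function(e)
        rep(NA_real_, length(observed)))
    }
    pval <- function(stat) {
      s <- stats::na.omit(samples[, stat])
      empirical_pvalue(observed[[stat]], s)
    }
    scalar <- c("n_groups", "r2_pc1", "r2_pc2", "fst", "kl", "a_corr",
                "gene_diversity")
    out$table1 <- data.frame(
      parameter = scalar,
      candidate = unname(observed[scalar]),
      null_mean = colMeans(samples[, scalar, drop = FALSE], na.rm = TRUE),
      p_value = vapply(scalar, pval, numeric(1)),
      row.names = NULL)
    bins <- paste0("maf_bin", 1:10)
    ci <- percentile_ci(samples[, bins, drop = FALSE])
    out$maf_bins <- data.frame(
      bin = names(maf_histogram(minor_allele_freq(cand_imp))),
      candidate = unname(observed[bins]),
      null_mean = ci$mean, low = ci$low, high = ci$high,
      outside = unname(observed[bins]) < ci$low |
                unname(observed[bins]) > ci$high,
      row.names = NULL)
    pcv <- paste0("pc_var", seq_len(pca_axes))
    civ <- percentile_ci(samples[, pcv, drop = FALSE])
    out$pc_r2 <- data.frame(
      axis = seq_len(pca_axes), candidate = unname(observed[pcv]),
      null_mean = civ$mean, low = civ$low, high = civ$high,
      outside = unname(observed[pcv]) < civ$low |
                unname(observed[pcv]) > civ$high,
      row.names = NULL)
    out$dist_var <- data.frame(candidate = observed[["dist_var"]],
                               null_mean = mean(samples[, "dist_var"],
                                                na.rm = TRUE),
                               p_value = pval("dist_var"))
    if ("redundancy" %in% stages) {
      tg <- paste0("tags_", format(thresholds))
      out$table2 <- data.frame(
        threshold = thresholds,
        candidate = unname(observed[tg]),
        null_mean = colMeans(samples[, tg, drop = FALSE], na.rm = TRUE),
        p_value = vapply(tg, pval, numeric(1)),
        row.names = NULL)
    }
    out$null_samples <- samples
    pc_ref <- marker_pca(ref_imp, k = pca_axes)
    pc_cand <- marker_pca(cand_imp, k = pca_axes)
    out$eigenvector_r2 <- eigenvector_r2(pc_cand, pc_ref, k = pca_axes)
  }

  if ("prediction" %in% stages && !is.null(phenotypes)) {
    say("prediction stage: %d traits, %d-fold CV, B_gs = %d",
        ncol(phenotypes), K, B_gs)
    part <- make_partition(rownames(phenotypes), K = K, seed = seed + 5L)
    acc_cand <- cross_validate_traits(phenotypes,
                                      realized_relationship(cand_imp), part)
    acc_ref <- cross_validate_traits(phenotypes, A_ref_full, part)
    cand_tags <- tag_snp_select(pairwise_r2(cand_imp), gs_tag_threshold,
                                colSums(is.na(unclass(cand))))$tags
    ref_tags <- tag_snp_select(pairwise_r2(ref_imp), gs_tag_threshold,
                               colSums(is.na(unclass(ref))))$tags
    acc_cand_tag <- cross_validate_traits(
      phenotypes, realized_relationship(cand_imp[, cand_tags]), part)
    acc_ref_tag <- cross_validate_traits(
      phenotypes, realized_relationship(ref_imp[, ref_tags]), part)

    gs_null <- function(pool, sz, offset) {
      arr <- matrix(NA_real_, B_gs, ncol(phenotypes),
                    dimnames = list(NULL, colnames(phenotypes)))
      for (b in seq_len(B_gs)) {
        sub <- subsample_markers(pool, sz, seed = seed + offset + b)
        arr[b, ] <- cross_validate_traits(phenotypes,
                                          realized_relationship(sub), part)
      }
      arr
    }
    null_all <- gs_null(ref_imp, size, 20000L)
    null_tag <- gs_null(ref_imp[, ref_tags],
                        min(length(cand_tags), length(ref_tags)), 40000L)
    out$table3 <- data.frame(
      trait = colnames(phenotypes),
      candidate_all = unname(acc_cand),
      candidate_tags = unname(acc_cand_tag),
      reference_all = unname(acc_ref),
      reference_tags = unname(acc_ref_tag),
      p_all = vapply(colnames(phenotypes), function(tr)
        empirical_pvalue(acc_cand[tr], stats::na.omit(null_all[, tr])),
        numeric(1)),
      p_tags = vapply(colnames(phenotypes), function(tr)
        empirical_pvalue(acc_cand_tag[tr], stats::na.omit(null_tag[, tr])),
        numeric(1)),
      row.names = NULL)
    out$partition <- part
    out$n_tags_gs <- c(candidate = length(cand_tags),
                       reference = length(ref_tags))
  }

  class(out) <- "platform_comparison"
  out
}

#' @export
print.platform_comparison <- function(x, ...) {
  cat("platform_comparison\n")
  cat(sprintf("  %d lines; %d reference markers (%.1f%% missing), %d candidate markers (%.1f%% missing)\n",
              x$n_lines, x$n_markers["reference"],
              100 * x$missing_rates["reference"],
              x$n_markers["candidate"], 100 * x$missing_rates["candidate"]))
  cat(sprintf("  subsampling null: B = %d subsets of %d reference markers\n",
              x$B, x$subsample_size))
  if (!is.null(x$table1)) {
    cat("\nDiversity statistics (candidate vs equal-size reference null):\n")
    print(x$table1, digits = 3)
  }
  if (!is.null(x$table2)) {
    cat("\nNon-redundant markers (tag SNPs):\n")
    print(x$table2, digits = 3)
  }
  if (!is.null(x$dist_var)) {
    cat("\nMarker distance variance:\n")
    print(x$dist_var, digits = 4)
  }
  if (!is.null(x$table3)) {
    cat("\nCross-validated prediction accuracy:\n")
    print(x$table3, digits = 2)
  }
  invisible(x)
}

#' @export
summary.platform_comparison <- function(object, ...) {
  sig <- c()
  if (!is.null(object$table1))
    sig <- c(sig, stats::setNames(object$table1$p_value < 0.05,
                                  object$table1$parameter))
  if (!is.null(object$table2))
    sig <- c(sig, stats::setNames(object$table2$p_value < 0.05,
                                  paste0("tags_", object$table2$threshold)))
  if (!is.null(object$dist_var))
    sig <- c(sig, dist_var = object$dist_var$p_value < 0.05)
  structure(list(comparison = object, significant = sig),
            class = "summary.platform_comparison")
}

#' @export
print.summary.platform_comparison <- function(x, ...) {
  print(x$comparison)
  cat("\nStatistics significant at 0.05 (possible ascertainment bias):\n  ")
  cat(if (any(x$significant)) paste(names(x$significant)[x$significant],
                                    collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Write a platform comparison to CSV tables and JSON
#'
#' Emits `table1.csv`, `table2.csv`, `table3.csv`, `maf_bins.csv`,
#' `pc_r2.csv`, `dist_var.csv`, `eigenvector_r2.csv` (those present)
#' plus `report.json` with provenance (seed, B, sizes).
#'
#' @param x a `platform_comparison`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(x, dir) {
  stopifnot(inherits(x, "platform_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("table1", "table2", "table3", "maf_bins", "pc_r2", "dist_var"))
    if (!is.null(x[[nm]]))
      utils::write.csv(x[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  if (!is.null(x$eigenvector_r2))
    utils::write.csv(x$eigenvector_r2, file.path(dir, "eigenvector_r2.csv"))
  prov <- list(seed = x$seed, B = x$B, B_gs = x$B_gs,
               n_lines = x$n_lines, n_markers = as.list(x$n_markers),
               subsample_size = x$subsample_size,
               missing_rates = as.list(x$missing_rates),
               version = as.character(utils::packageVersion("markerbias")))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(prov, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
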