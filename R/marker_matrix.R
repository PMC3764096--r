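#' Construct a marker score matrix
#'
#' A `marker_matrix` stores biallelic marker scores for a set of inbred
#' lines, coded \{aa, Aa, AA\} = \{-1, 0, 1\} with `NA` for missing calls.
#' Rows are lines, columns are markers; both carry unique identifiers.
#'
#' @param scores numeric matrix of scores in \{-1, 0, 1, NA\}.
#' @param line_ids character vector of unique line identifiers
#'   (default: rownames of `scores`).
#' @param marker_ids character vector of unique marker identifiers
#'   (default: colnames of `scores`).
#' @param platform free-text platform label (e.g. `"GBS"`, `"DArT"`).
#'
#' @return An object of class `marker_matrix`: a numeric matrix with
#'   `dimnames` set and a `platform` attribute.
#' @examples
#' m <- marker_matrix(rbind(c(-1, 1), c(0, NA)),
#'                    line_ids = c("L1", "L2"),
#'                    marker_ids = c("M1", "M2"), platform = "demo")
#' missing_rate(m)
#' @export
marker_matrix <- function(scores, line_ids = rownames(scores),
                          marker_ids = colnames(scores), platform = "unknown") {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(line_ids) || is.null(marker_ids))
    stop("line_ids and marker_ids are required")
  rownames(scores) <- as.character(line_ids)
  colnames(scores) <- as.character(marker_ids)
  attr(scores, "platform") <- platform
  class(scores) <- c("marker_matrix", "matrix", "array")
  validate_marker_matrix(scores)
}

#' Validate a marker score matrix
#'
#' Checks the `marker_matrix` invariants: at least 2 lines and 1 marker,
#' unique line and marker identifiers, and every non-missing score in
#' \{-1, 0, 1\}.
#'
#' @param m object to validate.
#' @return `m`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending cell or identifier.
#' @export
validate_marker_matrix <- function(m) {
  if (nrow(m) < 2L) stop("marker_matrix needs at least 2 lines")
  if (ncol(m) < 1L) stop("marker_matrix needs at least 1 marker")
  if (anyDuplicated(rownames(m)))
    stop("duplicated line IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicated marker IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(!is.na(m) & !(m == -1 | m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid score %s at line '%s', marker '%s' (must be -1, 0, 1 or missing)",
                 format(m[bad[1, 1], bad[1, 2]]),
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  m
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers (platform: %s)\n",
              nrow(x), ncol(x), attr(x, "platform")))
  cat(sprintf("missing: %.1f%%\n", 100 * missing_rate(x)))
  invisible(x)
}

#' Subset a marker matrix
#'
#' Subsetting keeps the `marker_matrix` class and platform attribute as
#' long as the result is still a matrix of at least 2 lines and 1 marker.
#'
#' @param x a `marker_matrix`.
#' @param i,j row (line) and column (marker) indices.
#' @param drop ignored; dimensions are always kept.
#' @param ... unused.
#' @export
`[.marker_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  attr(out, "platform") <- attr(x, "platform")
  class(out) <- class(x)
  out
}

#' Overall missing-data rate of a marker matrix
#'
#' The fraction of missing cells in the line-by-marker score matrix, where
#' a data point is one cell of the matrix.
#'
#' @param m a `marker_matrix`.
#' @return fraction in \[0, 1\].
#' @export
missing_rate <- function(m) {
  mean(is.na(unclass(m)))
}

#' Per-marker missing-data rates
#'
#' @param m a `marker_matrix`.
#' @return named numeric vector, one fraction per marker.
#' @export
marker_missing_rates <- function(m) {
  colMeans(is.na(unclass(m)))
}

#' Read a marker score matrix from disk
#'
#' Two dialects are supported. `"wide"`: a CSV with a line-ID first
#' column and one column per marker (header = marker IDs). `"hapmap"`:
#' a marker-per-row long format with columns `marker`, `chrom`, `pos`
#' followed by one column per line; the chromosome/position columns are
#' returned as a `map` attribute.
#'
#' @param path file to read.
#' @param dialect `"wide"` (default) or `"hapmap"`.
#' @param missing_token string encoding a missing call (default `"NA"`).
#' @param coding `"score"` for \{-1,0,1\} files, `"dosage"` for \{0,1,2\}
#'   files (recoded to scores as dosage - 1).
#' @param platform platform label to attach.
#' @return a validated `marker_matrix`; for the hapmap dialect, with a
#'   `map` attribute (data.frame of marker, chrom, pos).
#' @export
read_marker_matrix <- function(path, dialect = c("wide", "hapmap"),
                               missing_token = "NA",
                               coding = c("score", "dosage"),
                               platform = "unknown") {
  dialect <- match.arg(dialect)
  coding <- match.arg(coding)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = character(0))
  map <- NULL
  if (dialect == "wide") {
    ids <- df[[1]]
    raw <- as.matrix(df[, -1, drop = FALSE])
    rownames(raw) <- ids
  } else {
    need <- c("marker", "chrom", "pos")
    if (!all(need %in% names(df)))
      stop("hapmap dialect requires columns: ", paste(need, collapse = ", "))
    map <- data.frame(marker = df$marker, chrom = df$chrom,
                      pos = as.numeric(df$pos), stringsAsFactors = FALSE)
    raw <- t(as.matrix(df[, setdiff(names(df), need), drop = FALSE]))
    colnames(raw) <- df$marker
  }
  scores <- decode_scores(raw, missing_token, coding)
  m <- marker_matrix(scores, platform = platform)
  if (!is.null(map)) attr(m, "map") <- map
  m
}

decode_scores <- function(raw, missing_token, coding) {
  chr <- trimws(raw)
  chr[chr == missing_token] <- NA_character_
  allowed <- if (coding == "dosage") c("0", "1", "2") else c("-1", "0", "1")
  bad <- which(!is.na(chr) & !(chr %in% allowed), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid score '%s' at row '%s', column '%s' (allowed: %s or %s)",
                 chr[bad[1, 1], bad[1, 2]],
                 rownames(chr)[bad[1, 1]], colnames(chr)[bad[1, 2]],
                 paste(allowed, collapse = "/"), missing_token))
  }
  num <- matrix(as.numeric(chr), nrow(chr), ncol(chr), dimnames = dimnames(chr))
  if (coding == "dosage") num <- num - 1
  num
}

#' Write a marker score matrix to disk (wide CSV)
#'
#' Inverse of [read_marker_matrix()] for the wide dialect:
#' `read_marker_matrix(write_marker_matrix(m, path))` reproduces `m`,
#' including missing cells.
#'
#' @param m a valid `marker_matrix`.
#' @param path output file.
#' @param missing_token token written for missing cells (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path, missing_token = "NA") {
  validate_marker_matrix(m)
  chr <- matrix(as.character(unclass(m)), nrow(m), ncol(m))
  chr[is.na(chr)] <- missing_token
  df <- data.frame(line_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("line_id", colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table of line BLUEs
#'
#' A CSV with a line-ID first column and one column per trait. Values are
#' best linear unbiased estimators (BLUEs) of line means; missing values
#' are allowed and excluded from model training and accuracy for the
#' affected trait.
#'
#' @param path file to read.
#' @param missing_token string encoding a missing value (default `"NA"`).
#' @return a numeric matrix (lines x traits) with line IDs as rownames.
#' @export
read_phenotypes <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = character(0))
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated line IDs in phenotype table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  raw[trimws(raw) == missing_token] <- NA_character_
  y <- matrix(as.numeric(raw), nrow(raw), ncol(raw),
              dimnames = list(ids, colnames(raw)))
  ok <- colSums(!is.na(y)) > 0
  if (any(!ok))
    stop("trait(s) with no non-missing values: ",
         paste(colnames(y)[!ok], collapse = ", "))
  y
}

#' Write a phenotype table
#'
#' @param y numeric matrix (lines x traits) with line IDs as rownames.
#' @param path output file.
#' @param missing_token token written for missing values.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(y, path, missing_token = "NA") {
  chr <- matrix(as.character(y), nrow(y), ncol(y))
  chr[is.na(chr)] <- missing_token
  df <- data.frame(line_id = rownames(y), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("line_id", colnames(y))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align two marker matrices and a phenotype table on shared lines
#'
#' Lines are matched strictly by identifier, never by position; the
#' result is reindexed to the shared ID set in a common order.
#'
#' @param ref,cand `marker_matrix` objects for the same lines.
#' @param phenotypes optional phenotype matrix with line-ID rownames.
#' @return list with `ref`, `cand`, `phenotypes` (or `NULL`) restricted
#'   to shared lines in a common order.
#' @export
align_lines <- function(ref, cand, phenotypes = NULL) {
  shared <- intersect(rownames(ref), rownames(cand))
  if (!is.null(phenotypes)) shared <- intersect(shared, rownames(phenotypes))
  if (length(shared) < 2L)
    stop("fewer than 2 lines shared across inputs (matched by ID)")
  list(ref = ref[shared, ],
       cand = cand[shared, ],
       phenotypes = if (is.null(phenotypes)) NULL
                    else phenotypes[shared, , drop = FALSE])
}

#' Drop monomorphic markers
#'
#' Removes markers whose non-missing scores are all identical (or all
#' missing). Monomorphic markers are retained at read time and removed
#' only by this explicit filter.
#'
#' @param m a `marker_matrix`.
#' @return a `marker_matrix` containing only polymorphic markers.
#' @export
drop_monomorphic <- function(m) {
  poly <- apply(unclass(m), 2, function(x) length(unique(x[!is.na(x)])) >= 2)
  if (!any(poly)) stop("no polymorphic markers left")
  m[, poly]
}
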