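#' Read a feature count table
#'
#' Reads a delimited text file of sequencing read counts into the tidy count
#' table used throughout the package: a tibble whose first column,
#' `sample_id`, identifies samples and whose remaining columns are integer
#' feature counts. Sequencing depths are always taken as row sums of the
#' *full* table (before any prevalence filtering), so samples whose counts
#' sum to zero carry no information and are dropped with a warning.
#'
#' @param path Path to a TSV or CSV file with a header row and identifiers
#'   in the first column. The delimiter is chosen by extension (`.csv` =
#'   comma, otherwise tab).
#' @param orientation `"samples_as_rows"` (default) if rows are samples, or
#'   `"features_as_rows"` if the table is transposed on disk.
#' @return A tibble with a `sample_id` column and one numeric column per
#'   feature. Counts are validated to be non-negative integers; fractional
#'   values are an error, not rounded, because downstream models are count
#'   models.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows",
                                             "features_as_rows")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) abort("count table needs an id column and >= 1 feature.")
  ids <- as.character(raw[[1]])
  num <- raw[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vv <- as.numeric(v))
      bad <- which(is.na(vv) & !is.na(v))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric cell at row '%s', column '%s'.",
                      ids[bad[1]], names(num)[j]))
      }
      num[[j]] <- vv
    }
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "features_as_rows") {
    m <- t(m)
    rownames(m) <- colnames(num)
    colnames(m) <- ids
  }
  check_counts_valid(m, where = basename(path))
  depths <- rowSums(m)
  if (any(depths == 0)) {
    warn(sprintf("dropping %d sample(s) with zero sequencing depth: %s",
                 sum(depths == 0),
                 paste(rownames(m)[depths == 0], collapse = ", ")))
    m <- m[depths > 0, , drop = FALSE]
  }
  count_tibble(m)
}

#' Filter features by prevalence
#'
#' Prevalence of a feature is the fraction of samples in which its count is
#' non-zero. Features with prevalence greater than or equal to `threshold`
#' are retained (the boundary is inclusive), in their original order. The
#' operation is idempotent and monotone: raising the threshold never adds
#' features back.
#'
#' @param counts A count tibble (see [read_count_table()]) or matrix.
#' @param threshold Proportion in \[0, 1\].
#' @return A count tibble restricted to the retained features.
#' @export
filter_prevalence <- function(counts, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single proportion in [0, 1].")
  }
  m <- count_matrix(counts)
  prev <- colMeans(m > 0)
  count_tibble(m[, prev >= threshold, drop = FALSE])
}

#' Feature prevalence
#'
#' @param counts A count tibble or matrix.
#' @return Named numeric vector of per-feature prevalences.
#' @export
prevalence <- function(counts) {
  colMeans(count_matrix(counts) > 0)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal scores `qnorm((r - 3/8) / (n + 1/4))` using the
#' Blom offset, with mid-ranks for ties (tied inputs receive equal
#' transformed values). Standard normalisation for skewed continuous
#' covariates such as metabolite levels. The output depends on the input
#' only through ranks, so any strictly monotone transform of the input
#' yields identical output.
#'
#' @param values Numeric vector with at least two finite values.
#' @return Numeric vector of normal scores, mean approximately zero.
#' @export
rank_inverse_normal <- function(values) {
  if (!is.numeric(values)) abort("`values` must be numeric.")
  ok <- is.finite(values)
  if (sum(ok) < 2) abort("need at least 2 finite values.")
  x <- values[ok]
  if (diff(range(x)) == 0) {
    abort("all values identical: degenerate covariate cannot be transformed.")
  }
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

summary_stats_cols <- c("study_id", "feature_id", "beta_hat", "var_hat",
                        "n_samples", "prevalence", "converged")

#' Write / read per-study summary statistics
#'
#' The cross-study exchange format is a tab-delimited file with one header
#' line and columns `study_id`, `feature_id`, `beta_hat`, `var_hat`,
#' `n_samples`, `prevalence`, `converged`. Floating point values are
#' written at full precision so that a write/read round trip is lossless.
#' `read_summary_stats()` validates that every reported variance is
#' strictly positive.
#'
#' @param stats A summary-statistics tibble as produced by [palm_fit()].
#' @param path Output (or input) file path.
#' @return `write_summary_stats()` returns `stats` invisibly;
#'   `read_summary_stats()` returns a `palm_summary` tibble.
#' @export
write_summary_stats <- function(stats, path) {
  missing_cols <- setdiff(summary_stats_cols, names(stats))
  if (length(missing_cols) > 0) {
    abort(paste0("summary table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::select(as.data.frame(stats),
                       dplyr::all_of(summary_stats_cols))
  readr::write_tsv(out, path)
  invisible(stats)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  missing_cols <- setdiff(summary_stats_cols, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("summary file '", basename(path),
                 "' is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(tbl$var_hat) | tbl$var_hat <= 0)) {
    abort("summary file contains non-positive `var_hat`.")
  }
  new_palm_summary(tbl)
}

new_palm_summary <- function(tbl, shift = NULL) {
  tbl <- tibble::as_tibble(tbl)
  class(tbl) <- c("palm_summary", class(tbl))
  if (!is.null(shift)) attr(tbl, "shift") <- shift
  tbl
}
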