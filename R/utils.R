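# Internal coercions between the tidy count-table representation (tibble with
# a sample_id column followed by numeric feature columns) and the matrix form
# used by the numerical core.

count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
    }
    storage.mode(counts) <- "double"
    return(counts)
  }
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame or matrix.")
  }
  df <- as.data.frame(counts)
  id_col <- which(!vapply(df, is.numeric, logical(1)))
  if (length(id_col) > 1) {
    abort("`counts` may contain at most one non-numeric identifier column.")
  }
  if (length(id_col) == 1) {
    ids <- as.character(df[[id_col]])
    df <- df[, -id_col, drop = FALSE]
  } else if (!is.null(rownames(counts)) &&
             !identical(rownames(counts), as.character(seq_len(nrow(counts))))) {
    ids <- rownames(counts)
  } else {
    ids <- paste0("sample", seq_len(nrow(df)))
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

count_tibble <- function(m) {
  stopifnot(is.matrix(m))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

check_counts_valid <- function(m, where = "counts") {
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "%s: negative or non-numeric value at sample '%s', feature '%s'.",
      where, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  frac <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(frac) > 0) {
    abort(sprintf(
      "%s: non-integer count at sample '%s', feature '%s'; counts must be integral.",
      where, rownames(m)[frac[1, 1]], colnames(m)[frac[1, 2]]
    ))
  }
  if (anyDuplicated(rownames(m))) abort("duplicate sample identifiers.")
  if (anyDuplicated(colnames(m))) abort("duplicate feature identifiers.")
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
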