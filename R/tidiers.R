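#' Tidy and summarise result tables
#'
#' `tidy()` returns the underlying tibble (already one row per term);
#' `glance()` returns a one-row summary. For `palm_summary` objects the
#' glance reports the study's feature count, compositional shift and
#' variance range; for `palm_meta` it reports feature, study and discovery
#' counts.
#'
#' @param x A `palm_summary` or `palm_meta` object.
#' @param ... Unused.
#' @name palm-tidiers
NULL

#' @rdname palm-tidiers
#' @method tidy palm_summary
#' @export
tidy.palm_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "palm_summary")
  out
}

#' @rdname palm-tidiers
#' @method glance palm_summary
#' @export
glance.palm_summary <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_studies = dplyr::n_distinct(x$study_id),
    shift = attr(x, "shift") %||% NA_real_,
    median_var = median(x$var_hat),
    n_samples = max(x$n_samples)
  )
}

#' @rdname palm-tidiers
#' @method tidy palm_meta
#' @export
tidy.palm_meta <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "palm_meta")
  out
}

#' @rdname palm-tidiers
#' @method glance palm_meta
#' @export
glance.palm_meta <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    max_studies = max(x$n_studies),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_heterogeneous = sum(x$heterogeneous, na.rm = TRUE),
    fdr_level = attr(x, "fdr_level") %||% NA_real_,
    het_q_level = attr(x, "het_q_level") %||% NA_real_
  )
}
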