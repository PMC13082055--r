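#' Fixed-effect inverse-variance pooling for one feature
#'
#' Combines per-study effects \eqn{\hat\beta_\ell} with variances
#' \eqn{V_\ell} as \eqn{\hat\beta_{meta} = \sum(\hat\beta_\ell/V_\ell) /
#' \sum(1/V_\ell)}, \eqn{V_{meta} = 1/\sum(1/V_\ell)}; the association is
#' tested with \eqn{Q = \hat\beta_{meta}^2 / V_{meta}} against a chi-square
#' distribution with one degree of freedom.
#'
#' @param beta,var Numeric vectors of per-study effects and (positive)
#'   variances for one feature.
#' @return List with `beta_meta`, `var_meta`, `q_stat`, `p_value`.
#' @export
fixed_effect_meta <- function(beta, var) {
  if (length(beta) != length(var) || length(beta) < 1) {
    abort("`beta` and `var` must be non-empty and of equal length.")
  }
  if (any(!is.finite(var) | var <= 0)) abort("variances must be positive.")
  w <- 1 / var
  beta_meta <- sum(beta * w) / sum(w)
  var_meta <- 1 / sum(w)
  q_stat <- beta_meta^2 / var_meta
  list(beta_meta = beta_meta, var_meta = var_meta, q_stat = q_stat,
       p_value = pchisq(q_stat, df = 1, lower.tail = FALSE))
}

#' Cochran's Q heterogeneity test for one feature
#'
#' \eqn{Q_{het} = \sum_\ell (\hat\beta_\ell - \hat\beta_{meta})^2 / V_\ell}
#' compared against chi-square with L - 1 degrees of freedom. Requires at
#' least two studies.
#'
#' @inheritParams fixed_effect_meta
#' @param beta_meta Optional precomputed pooled effect; computed if `NULL`.
#' @return List with `het_q_stat`, `het_df`, `het_p`.
#' @export
cochran_q <- function(beta, var, beta_meta = NULL) {
  if (length(beta) < 2) abort("heterogeneity needs >= 2 studies.")
  if (is.null(beta_meta)) beta_meta <- fixed_effect_meta(beta, var)$beta_meta
  q <- sum((beta - beta_meta)^2 / var)
  df <- length(beta) - 1L
  list(het_q_stat = q, het_df = df,
       het_p = pchisq(q, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values over a p-value vector; missing values are excluded
#' from the adjustment and returned missing.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

#' Meta-analyse per-study AA summary statistics
#'
#' Assembles, for every feature, the set of studies in which it was
#' observed (matching by exact feature id), pools the AA-level effects by
#' fixed-effect inverse-variance weighting, tests association (chi-square,
#' 1 df), assesses between-study heterogeneity with Cochran's Q, and
#' applies BH correction over features — separately for association and
#' heterogeneity p-values. Features seen in a single study carry no
#' heterogeneity assessment.
#'
#' @param stats A single summary tibble (possibly covering several
#'   `study_id`s) or a list of per-study tibbles as produced by
#'   [palm_fit()] or [read_summary_stats()].
#' @param fdr_level Discovery threshold on the association q-value
#'   (default 0.05; discoveries are `q_value <= fdr_level`).
#' @param het_q_level Threshold on the heterogeneity q-value (default 0.1,
#'   strict inequality).
#' @return A `palm_meta` tibble with one row per feature: `feature_id`,
#'   `n_studies`, `beta_meta`, `var_meta`, `q_stat`, `p_value`, `q_value`,
#'   `het_q_stat`, `het_df`, `het_p`, `het_q`, `significant`,
#'   `heterogeneous`.
#' @export
palm_meta <- function(stats, fdr_level = 0.05, het_q_level = 0.1) {
  if (is.data.frame(stats)) stats <- list(stats)
  tbl <- dplyr::bind_rows(lapply(stats, tibble::as_tibble))
  needed <- c("study_id", "feature_id", "beta_hat", "var_hat")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("summary statistics are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- dplyr::count(tbl, .data$study_id, .data$feature_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("feature '%s' appears more than once in study '%s'.",
                  dup$feature_id[1], dup$study_id[1]))
  }
  if (any(!is.finite(tbl$var_hat) | tbl$var_hat <= 0)) {
    abort("non-positive `var_hat` in summary statistics.")
  }

  out <- tbl |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::group_modify(function(d, key) {
      fe <- fixed_effect_meta(d$beta_hat, d$var_hat)
      het <- if (nrow(d) >= 2) {
        cochran_q(d$beta_hat, d$var_hat, beta_meta = fe$beta_meta)
      } else {
        list(het_q_stat = NA_real_, het_df = NA_integer_, het_p = NA_real_)
      }
      tibble::tibble(n_studies = nrow(d), beta_meta = fe$beta_meta,
                     var_meta = fe$var_meta, q_stat = fe$q_stat,
                     p_value = fe$p_value, het_q_stat = het$het_q_stat,
                     het_df = het$het_df, het_p = het$het_p)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$feature_id) |>
    dplyr::mutate(q_value = bh_adjust(.data$p_value),
                  het_q = bh_adjust(.data$het_p),
                  significant = .data$q_value <= fdr_level,
                  heterogeneous = !is.na(.data$het_q) &
                    .data$het_q < het_q_level) |>
    dplyr::relocate("q_value", .after = "p_value")
  class(out) <- c("palm_meta", class(out))
  attr(out, "fdr_level") <- fdr_level
  attr(out, "het_q_level") <- het_q_level
  out
}

#' Run a meta-analysis from summary-statistic files
#'
#' Reads one or more per-study summary TSVs (see [read_summary_stats()])
#' and calls [palm_meta()]. Study order is immaterial.
#'
#' @param stat_files Character vector of file paths.
#' @inheritParams palm_meta
#' @return A `palm_meta` tibble.
#' @export
run_meta <- function(stat_files, fdr_level = 0.05, het_q_level = 0.1) {
  if (length(stat_files) < 1) abort("need at least one summary file.")
  palm_meta(lapply(stat_files, read_summary_stats),
            fdr_level = fdr_level, het_q_level = het_q_level)
}
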