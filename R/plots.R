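#' Plot per-study AA summary statistics
#'
#' Caterpillar plot of AA-level effect estimates with 95% normal
#' intervals, ordered by effect size. Useful as a quick per-study sanity
#' check before meta-analysis.
#'
#' @param object A `palm_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot palm_summary
#' @export
autoplot.palm_summary <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(
      lo = .data$beta_hat - 1.96 * sqrt(.data$var_hat),
      hi = .data$beta_hat + 1.96 * sqrt(.data$var_hat),
      feature_id = stats::reorder(.data$feature_id, .data$beta_hat)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_hat,
                                  y = .data$feature_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0, colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "AA-level effect (log scale)", y = NULL,
                  title = unique(d$study_id)[1]) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Volcano plot of meta-analysis results
#'
#' Pooled AA effect against -log10 association p-value; discoveries at
#' the configured FDR level are highlighted and features with significant
#' between-study heterogeneity are marked.
#'
#' @param object A `palm_meta` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot palm_meta
#' @export
autoplot.palm_meta <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$significant & .data$heterogeneous ~ "discovery (heterogeneous)",
        .data$significant ~ "discovery",
        TRUE ~ "not significant"
      )
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_meta,
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.8, size = 1.3) +
    ggplot2::scale_colour_manual(values = c(
      "discovery" = "#B2182B",
      "discovery (heterogeneous)" = "#E69F00",
      "not significant" = "grey55"
    )) +
    ggplot2::labs(x = "pooled AA-level effect (log scale)",
                  y = expression(-log[10] ~ "p-value"), colour = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}
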