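#' Per-study AA-level summary statistics
#'
#' The full single-study pipeline: for every feature, fit the Firth
#' quasi-Poisson null model once (intercept + confounders, log-depth
#' offset), form the score-statistic RA-level effect and its sandwich
#' variance against the covariate of interest (clustered when cluster ids
#' are given), then remove the common compositional shift by the median of
#' the RA effects and calibrate variances for the variability of the
#' median. The result is the study's exchangeable unit: AA-level summary
#' statistics ready for [palm_meta()].
#'
#' Sequencing depths default to row sums of the *unfiltered* count table,
#' so prevalence filtering never changes the offsets; a depth column in
#' `metadata` overrides. Features whose null fit fails to converge, whose
#' effect is not identifiable, or whose sandwich variance degenerates to
#' zero are excluded from the output (they simply drop out of the
#' feature's study set at meta-analysis).
#'
#' @param counts Count tibble (see [read_count_table()]) or samples x
#'   features matrix.
#' @param metadata Data frame with one row per sample. Matched to counts
#'   by a `sample_id` column when present (otherwise by position, with a
#'   row-count check).
#' @param covariate Name of the covariate-of-interest column in
#'   `metadata`.
#' @param confounders Optional character vector of confounder column
#'   names.
#' @param cluster Optional name of a cluster-id column; switches the
#'   sandwich to its clustered form.
#' @param depth Optional name of a depth column overriding row sums.
#' @param prev_threshold Within-study prevalence filter applied before
#'   fitting (default 0: no filtering, matching the convention that
#'   prevalence filters are applied externally).
#' @param study_id Study label stamped on every output row.
#' @param k_floor Warn when fewer features than this survive to the
#'   compositional correction (default 20).
#' @return A `palm_summary` tibble with columns `study_id`, `feature_id`,
#'   `beta_hat`, `var_hat`, `n_samples`, `prevalence`, `converged`, plus
#'   the RA-level `beta_star`, `var_star`. The study-level compositional
#'   shift is in `attr(, "shift")`.
#' @examples
#' sim <- simulate_meta_experiment(sim_config(n_studies = 1,
#'                                            n_samples = 50,
#'                                            n_features = 40, seed = 7))
#' st <- sim$studies[[1]]
#' palm_fit(st$counts, st$design, covariate = "group")
#' @export
palm_fit <- function(counts, metadata, covariate, confounders = NULL,
                     cluster = NULL, depth = NULL, prev_threshold = 0,
                     study_id = "study1", k_floor = 20L) {
  m <- count_matrix(counts)
  check_counts_valid(m)
  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% names(metadata)) {
    miss <- setdiff(rownames(m), metadata$sample_id)
    if (length(miss) > 0) {
      abort(sprintf("metadata is missing sample(s): %s",
                    paste(head(miss, 3), collapse = ", ")))
    }
    metadata <- metadata[match(rownames(m), metadata$sample_id), ,
                         drop = FALSE]
  } else if (nrow(metadata) != nrow(m)) {
    abort("metadata and counts disagree on the number of samples.")
  }
  for (col in c(covariate, confounders, cluster, depth)) {
    if (!col %in% names(metadata)) {
      abort(sprintf("column '%s' not found in metadata.", col))
    }
  }

  depths <- if (is.null(depth)) rowSums(m) else as.numeric(metadata[[depth]])
  keep <- depths > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d sample(s) with zero depth.", sum(!keep)))
    m <- m[keep, , drop = FALSE]
    metadata <- metadata[keep, , drop = FALSE]
    depths <- depths[keep]
  }

  x <- as.numeric(metadata[[covariate]])
  if (any(!is.finite(x))) abort("covariate has non-finite values.")
  if (stats::var(x) == 0) abort("covariate has zero variance.")
  cf <- if (is.null(confounders)) NULL else {
    cm <- as.matrix(as.data.frame(lapply(metadata[confounders], as.numeric)))
    colnames(cm) <- confounders
    cm
  }
  cl <- if (is.null(cluster)) NULL else as.character(metadata[[cluster]])

  if (prev_threshold > 0) {
    m_fit <- count_matrix(filter_prevalence(m, prev_threshold))
  } else {
    m_fit <- m
  }
  prev <- colMeans(m_fit > 0)
  # a feature never seen in this study is unobserved here, not a zero effect:
  # it contributes no summary row and drops out of its cross-study set
  if (any(prev == 0)) {
    inform(sprintf("%d feature(s) unobserved in this study were excluded.",
                   sum(prev == 0)))
    m_fit <- m_fit[, prev > 0, drop = FALSE]
    prev <- prev[prev > 0]
  }

  eff_n <- nrow(m_fit)
  per_feature <- purrr::map(colnames(m_fit), function(fid) {
    tryCatch({
      fit <- fit_null(m_fit[, fid], depths, confounders = cf)
      if (!fit$converged) abort("null fit did not converge.")
      eff <- score_effect(fit, x)
      v <- if (is.null(cl)) sandwich_independent(fit, x)
           else sandwich_clustered(fit, x, cl)
      # guard against exact degeneracy (all Firth residuals zero) and its
      # floating-point shadow
      if (!is.finite(v) || v <= 1e-12 / eff_n) {
        abort("degenerate sandwich variance.")
      }
      tibble::tibble(feature_id = fid, beta_star = eff$beta_star,
                     var_star = v, converged = TRUE)
    }, error = function(e) {
      inform(sprintf("feature '%s' excluded: %s", fid, conditionMessage(e)))
      NULL
    })
  })
  ra <- dplyr::bind_rows(per_feature)
  if (nrow(ra) < 2) {
    abort("fewer than 2 features produced valid RA summaries.")
  }
  aa <- recover_aa(ra$beta_star, ra$var_star, k_floor = k_floor)
  out <- dplyr::bind_cols(
    tibble::tibble(study_id = study_id),
    ra["feature_id"],
    aa[c("beta_hat", "var_hat")],
    tibble::tibble(n_samples = nrow(m_fit),
                   prevalence = unname(prev[ra$feature_id]),
                   converged = ra$converged,
                   beta_star = ra$beta_star, var_star = ra$var_star)
  )
  new_palm_summary(out, shift = aa$shift[1])
}
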