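# Score-statistic effects and sandwich variances against a single null fit.
#
# With null fit (mu~, h~) and Firth-adjusted residuals r_i = Y_i - mu~_i +
# h~_i/2, the quasi-score for a covariate X partitions as S1 = sum r_i X_i
# (covariate block) and S0 = sum r_i x~_i (null block, zero at the fit). The
# quasi-information of the full design [X | null] at the null fit is
# I = sum mu~_i [X_i; x~_i][X_i; x~_i]^T, and the effective information for
# the covariate is I1 = I11 - I10 I00^{-1} I01. The score-statistic effect
# estimate is beta* = S1 / I1 (one-step Taylor approximation to the full
# quasi-score root), with robust variance from per-sample score
# contributions U_i = r_i (X_i - x~_i^T I00^{-1} I01).

score_parts <- function(fit, x) {
  if (!inherits(fit, "palm_nullfit")) abort("`fit` must be a palm_nullfit.")
  if (!fit$converged) abort("null fit did not converge.")
  x <- as.numeric(x)
  if (length(x) != length(fit$y)) abort("covariate length mismatch.")
  if (any(!is.finite(x))) abort("covariate has non-finite values.")
  if (stats::var(x) == 0) abort("covariate is constant: effect not identifiable.")
  mu <- fit$mu
  xn <- fit$design
  i00 <- crossprod(xn * sqrt(mu))
  ch <- tryCatch(chol(i00), error = function(e) {
    abort("null information is singular.")
  })
  d <- diag(ch)
  if ((max(d) / min(d))^2 > 1e12) abort("null information is ill conditioned.")
  i01 <- drop(crossprod(xn, mu * x))
  a <- backsolve(ch, backsolve(ch, i01, transpose = TRUE))
  i11 <- sum(mu * x^2)
  info_eff <- i11 - sum(i01 * a)
  if (!is.finite(info_eff) || info_eff <= 1e-10 * max(i11, 1)) {
    abort("covariate lies in the span of the null design: effect not identifiable.")
  }
  u <- fit$resid * (x - drop(xn %*% a))
  list(s1 = sum(fit$resid * x), info_eff = info_eff, u = u)
}

#' Score-statistic estimate of the relative-abundance effect
#'
#' Estimates the RA-level association \eqn{\hat\beta^* = \mathcal{I}_1^{-1}
#' S_1(\tilde\theta)} of a covariate from a feature's null fit, where
#' \eqn{S_1} is the covariate block of the Firth quasi-score evaluated at
#' the null estimate and \eqn{\mathcal{I}_1 = \mathcal{I}_{11} -
#' \mathcal{I}_{10}\mathcal{I}_{00}^{-1}\mathcal{I}_{01}} is the effective
#' quasi-information. No per-covariate model refit is needed, which is what
#' makes large covariate scans cheap.
#'
#' @param fit A converged [fit_null()] object.
#' @param x Numeric covariate of interest (finite, non-constant).
#' @return A list with `beta_star`, `info_eff` and the score `s1`.
#' @export
score_effect <- function(fit, x) {
  p <- score_parts(fit, x)
  list(beta_star = p$s1 / p$info_eff, info_eff = p$info_eff, s1 = p$s1)
}

#' Sandwich variance of the score-statistic effect
#'
#' Model-robust variance \eqn{V^* = \mathcal{I}_1^{-1} (\sum_i U_i^2)
#' \mathcal{I}_1^{-1}} from the empirical outer product of per-sample score
#' contributions \eqn{U_i = S_{1,i} -
#' \mathcal{I}_{10}\mathcal{I}_{00}^{-1} S_{0,i}} (Firth term retained in
#' the residual). `sandwich_clustered()` sums contributions within clusters
#' before squaring, which is the standard adjustment for correlated samples
#' (longitudinal, repeated measures, family data); with singleton clusters
#' it reduces exactly to the independent form. No small-sample correction
#' is applied for very few clusters (< 10); interpret such variances with
#' care.
#'
#' @inheritParams score_effect
#' @param cluster_ids Vector of cluster labels, one per sample.
#' @return The sandwich variance (scalar). Zero (degenerate: all residuals
#'   vanish) is returned as-is; callers flag it.
#' @export
sandwich_independent <- function(fit, x) {
  p <- score_parts(fit, x)
  sum(p$u^2) / p$info_eff^2
}

#' @rdname sandwich_independent
#' @export
sandwich_clustered <- function(fit, x, cluster_ids) {
  if (length(cluster_ids) != length(fit$y)) {
    abort("`cluster_ids` length mismatch.")
  }
  p <- score_parts(fit, x)
  cl_sums <- rowsum(p$u, group = as.character(cluster_ids))
  sum(cl_sums^2) / p$info_eff^2
}

#' Scan many covariates against per-feature null fits
#'
#' Reuses each feature's single null fit across all columns of a covariate
#' matrix; results are identical to calling [score_effect()] and the
#' sandwich estimator pair by pair. Failures (constant covariate,
#' non-identifiable pair, ...) are recorded per pair and the scan
#' continues.
#'
#' @param fits Named list of [fit_null()] objects (names are feature ids),
#'   all fitted on the same samples.
#' @param covariates Numeric matrix (samples x covariates) or vector.
#' @param cluster_ids Optional cluster labels; when supplied the clustered
#'   sandwich is used.
#' @return A tibble with one row per (feature, covariate) pair: `feature_id`,
#'   `covariate`, `beta_star`, `var_star`, `info_eff`, `error` (NA when the
#'   pair succeeded).
#' @export
score_scan <- function(fits, covariates, cluster_ids = NULL) {
  if (inherits(fits, "palm_nullfit")) fits <- list(feature = fits)
  if (is.null(names(fits))) names(fits) <- paste0("feature", seq_along(fits))
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
  }
  grid <- tidyr::expand_grid(feature_id = names(fits),
                             covariate = colnames(covariates))
  res <- purrr::pmap(grid, function(feature_id, covariate) {
    fit <- fits[[feature_id]]
    x <- covariates[, covariate]
    tryCatch({
      eff <- score_effect(fit, x)
      v <- if (is.null(cluster_ids)) sandwich_independent(fit, x)
           else sandwich_clustered(fit, x, cluster_ids)
      tibble::tibble(beta_star = eff$beta_star, var_star = v,
                     info_eff = eff$info_eff, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(beta_star = NA_real_, var_star = NA_real_,
                     info_eff = NA_real_, error = conditionMessage(e))
    })
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}
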