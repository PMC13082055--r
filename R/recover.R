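#' Estimate the compositional shift
#'
#' Relative-abundance effects equal the absolute-abundance effects shifted
#' by a common compositional term induced by covariate-associated changes
#' in total microbial load. Under the sparsity assumption that most
#' features carry no AA-level effect, the negated shift is estimated by the
#' median of the per-feature RA effects; the median is robust to the
#' minority of genuinely differential (possibly extreme) features. For even
#' numbers of features the midpoint of the two central order statistics is
#' used.
#'
#' @param beta_stars Numeric vector of RA-level effect estimates, one per
#'   feature (length >= 2).
#' @return The estimated shift (scalar).
#' @export
compositional_shift <- function(beta_stars) {
  b <- beta_stars[is.finite(beta_stars)]
  if (length(b) < 2) {
    abort("need >= 2 features to estimate the compositional shift.")
  }
  median(b)
}

#' Recover absolute-abundance summary statistics
#'
#' Converts RA-level per-feature summaries to AA-level ones:
#' \eqn{\hat\beta_k = \hat\beta_k^* - \mathrm{median}_j\{\hat\beta_j^*\}},
#' with the variance calibrated for the variability of the median,
#' \deqn{V_k = V_k^* + \frac{K}{4\left(\sum_j (2\pi V_j^*)^{-1/2}\right)^2}.}
#' The additive calibration term is common to all features of a study; in
#' the equal-variance case it reduces to \eqn{\pi V^*/(2K)}, the classical
#' asymptotic variance of the median of K independent normal draws, and it
#' vanishes at rate 1/K. The sparsity assumption behind the median becomes
#' fragile for very few features; a warning is emitted below `k_floor`.
#'
#' @param beta_star,var_star Numeric vectors of RA-level effects and their
#'   sandwich variances (all variances strictly positive).
#' @param k_floor Feature count below which a warning is issued (default
#'   20).
#' @return A tibble with columns `beta_hat`, `var_hat` and the common
#'   `shift`, one row per feature, in input order.
#' @export
recover_aa <- function(beta_star, var_star, k_floor = 20L) {
  if (length(beta_star) != length(var_star)) {
    abort("`beta_star` and `var_star` lengths differ.")
  }
  if (any(!is.finite(var_star) | var_star <= 0)) {
    abort("all `var_star` must be finite and strictly positive.")
  }
  k <- length(beta_star)
  if (k < 2) abort("compositional correction undefined for < 2 features.")
  if (k < k_floor) {
    warn(sprintf(paste0("only %d features: the sparse-signal assumption ",
                        "behind the median shift is fragile."), k))
  }
  shift <- compositional_shift(beta_star)
  inflation <- k / (4 * sum(1 / sqrt(2 * pi * var_star))^2)
  tibble::tibble(beta_hat = beta_star - shift,
                 var_hat = var_star + inflation,
                 shift = shift)
}
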