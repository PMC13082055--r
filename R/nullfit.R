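#' Leverages of a weighted design
#'
#' Diagonal of the hat matrix \eqn{H = W^{1/2} X (X^\top W X)^{-1} X^\top
#' W^{1/2}} with Poisson working weights \eqn{W = \mathrm{diag}(\mu)}:
#' \eqn{h_i = \mu_i x_i^\top (X^\top W X)^{-1} x_i}. These leverages drive
#' the Firth penalty term \eqn{+h_i/2} in the quasi-score. They satisfy
#' \eqn{0 \le h_i \le 1} and sum to the column rank of the design.
#'
#' @param mu Positive vector of fitted means.
#' @param design Numeric matrix, n x q, full column rank.
#' @return Numeric vector of leverages.
#' @export
hat_diagonals <- function(mu, design) {
  design <- as.matrix(design)
  if (any(mu <= 0)) abort("`mu` must be strictly positive.")
  xtwx <- crossprod(design * sqrt(mu))
  ch <- tryCatch(chol(xtwx), error = function(e) {
    abort("design is rank deficient (collinear columns).")
  })
  d <- diag(ch)
  if ((max(d) / min(d))^2 > 1e12) {
    abort("design is numerically rank deficient (collinear columns).")
  }
  # h_i = mu_i * || solve(t(R), x_i) ||^2
  v <- backsolve(ch, t(design), transpose = TRUE)
  as.vector(mu * colSums(v^2))
}

#' Fit the Firth-corrected quasi-Poisson null model for one feature
#'
#' Solves the Firth-penalised quasi-score equations
#' \deqn{\sum_i (Y_i - \mu_i + h_i/2)\, \tilde x_i = 0, \qquad
#'       \mu_i = N_i \exp(\tilde x_i^\top \theta),}
#' over the *null* design (intercept plus confounders; never the covariate
#' of interest) with a log-depth offset, by Newton iteration on the
#' quasi-information with step halving. The Firth term keeps boundary
#' features (e.g. all-zero counts) finite: with an intercept-only design
#' the fixed point is \eqn{\sum_i \mu_i = \sum_i Y_i + 1/2}, i.e.
#' \eqn{e^{\hat\beta_0} = (\sum Y + 1/2)/\sum N}. The overdispersion
#' \eqn{\phi} of the quasi-Poisson variance \eqn{\phi\mu} cancels from the
#' score equations and is never estimated; all downstream uncertainty flows
#' through the sandwich variance.
#'
#' The fit does not reference any covariate of interest, so one null fit
#' per feature serves an arbitrary number of covariate scans.
#'
#' @param y Integer count vector for one feature.
#' @param depths Positive sequencing depths \eqn{N_i}.
#' @param confounders Optional numeric matrix of confounders (the intercept
#'   is added internally).
#' @param max_iter,score_tol,step_tol Iteration controls: convergence when
#'   the maximum absolute score drops below `score_tol` or the relative
#'   coefficient change below `step_tol`.
#' @return An object of class `palm_nullfit`: coefficients `theta`, fitted
#'   means `mu`, leverages `hat_diag`, Firth-adjusted residuals `resid`
#'   (`y - mu + hat_diag/2`), the null design, convergence flag and
#'   iteration count.
#' @export
fit_null <- function(y, depths, confounders = NULL,
                     max_iter = 100L, score_tol = 1e-8, step_tol = 1e-10) {
  y <- as.numeric(y)
  n <- length(y)
  if (length(depths) != n) abort("`y` and `depths` lengths differ.")
  if (any(!is.finite(depths) | depths <= 0)) {
    abort("`depths` must be positive and finite.")
  }
  design <- cbind(intercept = rep(1, n))
  if (!is.null(confounders)) {
    cf <- as.matrix(confounders)
    if (nrow(cf) != n) abort("`confounders` has wrong number of rows.")
    if (is.null(colnames(cf))) {
      colnames(cf) <- paste0("confounder", seq_len(ncol(cf)))
    }
    design <- cbind(design, cf)
  }
  q0 <- ncol(design)
  if (qr(design)$rank < q0) {
    abort("null design is rank deficient: collinear confounders.")
  }
  if (n < q0 + 1) abort("fewer samples than null parameters + 1.")
  off <- log(depths)

  theta <- c(log((sum(y) + q0 / 2) / sum(depths)), rep(0, q0 - 1))
  eta <- off + drop(design %*% theta)
  mu <- exp(eta)
  h <- hat_diagonals(mu, design)
  s <- drop(crossprod(design, y - mu + h / 2))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    if (max(abs(s)) < score_tol) { converged <- TRUE; break }
    iter <- iter + 1L
    info <- crossprod(design * sqrt(mu))
    step <- tryCatch(solve(info, s), error = function(e) {
      abort("quasi-information is singular; cannot take Newton step.")
    })
    s_norm <- sum(s^2)
    lambda <- 1
    repeat {
      theta_new <- theta + lambda * step
      mu_new <- exp(off + drop(design %*% theta_new))
      h_new <- hat_diagonals(mu_new, design)
      s_new <- drop(crossprod(design, y - mu_new + h_new / 2))
      if (sum(s_new^2) <= s_norm || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    rel_step <- max(abs(theta_new - theta) / pmax(abs(theta), 1))
    theta <- theta_new; mu <- mu_new; h <- h_new; s <- s_new
    if (rel_step < step_tol) { converged <- TRUE; break }
  }
  if (max(abs(s)) < score_tol) converged <- TRUE
  structure(
    list(theta = setNames(theta, colnames(design)), mu = mu, hat_diag = h,
         resid = y - mu + h / 2, design = design, y = y, depths = depths,
         converged = converged, iterations = iter,
         score_norm = max(abs(s))),
    class = "palm_nullfit"
  )
}

#' @export
print.palm_nullfit <- function(x, ...) {
  cat("Firth quasi-Poisson null fit:", length(x$y), "samples,",
      ncol(x$design), "null parameter(s);",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iteration(s)\n")
  print(x$theta)
  invisible(x)
}
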