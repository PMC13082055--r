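# Independent oracles used by the test suite. These deliberately avoid the
# package's own iteration/linear-algebra paths.

# Root of the Firth quasi-score over the full design (intercept + x), with
# the Firth adjustment term held at the null-fit leverages — the function
# whose Taylor expansion at the null fit defines the score estimator.
# Solved by generic derivative-free/BFGS minimisation of the squared score.
oracle_quasi_root <- function(y, depths, x, fit) {
  X <- cbind(1, x)
  hfix <- fit$hat_diag
  obj <- function(th) {
    mu <- as.vector(depths * exp(X %*% th))
    sum(drop(crossprod(X, y - mu + hfix / 2))^2)
  }
  o <- stats::optim(c(fit$theta[1], 0), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 5000))
  o <- stats::optim(o$par, obj, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 1000))
  # accept roots located to |score| <= 1e-7, i.e. well inside the 1e-8
  # slack of the agreement bound
  if (o$value > 1e-14) return(NULL)
  o$par
}

# Root of the *literal* full-model Firth quasi-score, leverages re-evaluated
# from the full design at every theta. Used to document the (small)
# difference between the two leverage conventions.
oracle_full_firth_root <- function(y, depths, x) {
  X <- cbind(1, x)
  obj <- function(th) {
    mu <- as.vector(depths * exp(X %*% th))
    q <- qr.Q(qr(X * sqrt(mu)))
    h <- rowSums(q^2)
    sum(drop(crossprod(X, y - mu + h / 2))^2)
  }
  o <- stats::optim(c(log((sum(y) + 1) / sum(depths)), 0), obj,
                    method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 5000))
  o <- stats::optim(o$par, obj, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 1000))
  if (o$value > 1e-16) return(NULL)
  o$par
}

# Textbook step-up BH, written directly from the definition
# q_(i) = min_{j >= i} m p_(j) / j, independent of stats::p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small random study for pipeline-level tests: returns counts matrix,
# design tibble and depths.
toy_study <- function(n = 60, k = 30, seed = 1, effect = NULL) {
  set.seed(seed)
  mu <- make_baseline(k, 1.5)
  mu1 <- mu
  if (!is.null(effect)) {
    mu1[effect$idx] <- mu1[effect$idx] * effect$fold
    mu1 <- mu1 / sum(mu1)
  }
  simulate_study(mu, mu1, n, dirichlet_scale = 100,
                 depth_meanlog = 8.5, depth_sdlog = 0.3, depth_min = 1000)
}
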