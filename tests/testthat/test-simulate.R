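test_that("configurations are validated", {
  expect_error(sim_config(n_samples = c(99, 100, 100, 100, 100)), "even")
  expect_error(sim_config(prop_active = 0.6), "0, 0.5")
  expect_error(sim_config(max_fold = 1), "exceed 1")
  expect_error(sim_config(n_samples = c(10, 10)), "per study")
  cfg <- sim_config(n_studies = 3, n_samples = 50)
  expect_equal(cfg$n_samples, rep(50L, 3))
})

test_that("baselines are valid proportion vectors with the expected abundance split", {
  set.seed(40)
  mu <- make_baseline(200)
  expect_equal(sum(mu), 1, tolerance = 1e-12)
  expect_true(all(mu > 0))
  expect_error(make_baseline(1), "at least 2")
  # near-uniform limit
  set.seed(40)
  expect_equal(make_baseline(2, 1e-8), c(0.5, 0.5), tolerance = 1e-6)
  # at sigma = 2.5 and K = 401, a modest fraction of features is above 1e-3
  set.seed(41)
  fr <- replicate(1000, mean(make_baseline(401, 2.5) >= 1e-3))
  expect_gte(median(fr), 0.05)
  expect_lte(median(fr), 0.30)
})

test_that("active-feature choice respects strata, quotas and sign schemes", {
  mu <- c(rep(0.015, 60), rep(1e-5, 40))
  mu <- mu / sum(mu)  # 60 abundant, 40 rare at the 1e-3 cut
  set.seed(42)
  act <- choose_active(mu, 0.1)
  expect_equal(nrow(act), 10)
  expect_equal(sum(act$abundant), 5)
  expect_equal(sum(!act$abundant), 5)
  expect_true(all(act$sign %in% c(-1, 1)))
  pos <- choose_active(mu, 0.1, effect_direction = "positive")
  expect_true(all(pos$sign == 1))
  # quota violation
  mu_bad <- c(rep(0.3, 3), rep(7e-4, 97))
  mu_bad <- mu_bad / sum(mu_bad)
  expect_error(choose_active(mu_bad, 0.2), "abundant stratum")
})

test_that("spike-in renormalises exactly and keeps inactive truth at zero", {
  sp <- spike_in(c(0.5, 0.3, 0.2), active = 1L, folds = 2, signs = 1)
  expect_equal(sp$mu1, c(1, 0.3, 0.2) / 1.5, tolerance = 1e-12)
  expect_equal(sp$mu0, c(0.5, 0.3, 0.2), tolerance = 1e-12)
  expect_equal(sp$true_log_effect, c(log(2), 0, 0))
  # negative effects inflate the reference group instead
  sn <- spike_in(c(0.5, 0.3, 0.2), active = 2L, folds = 3, signs = -1)
  expect_equal(sn$mu0, c(0.5, 0.9, 0.2) / 1.6, tolerance = 1e-12)
  expect_equal(sn$true_log_effect[2], -log(3))
  # no active features: identity
  s0 <- spike_in(c(0.4, 0.6), integer(0), numeric(0), numeric(0))
  expect_equal(s0$mu0, s0$mu1)
  expect_equal(s0$true_log_effect, c(0, 0))
})

test_that("study generation respects depths, groups and spiked ratios", {
  set.seed(43)
  mu <- make_baseline(50, 1.5)
  st <- simulate_study(mu, mu, 20)
  m <- as.matrix(st$counts[, -1])
  expect_equal(nrow(m), 20)
  expect_equal(as.integer(table(st$design$group)), c(10L, 10L))
  expect_true(all(rowSums(m) >= 2000))
  expect_error(simulate_study(mu, mu, 21), "even")
  # law of large numbers: strong spike recovered in group mean RA
  set.seed(44)
  sp <- spike_in(mu, active = which.max(mu), folds = 5, signs = 1)
  st2 <- simulate_study(sp$mu0, sp$mu1, 500, dirichlet_scale = 50,
                        depth_meanlog = log(5e4), depth_sdlog = 0,
                        depth_min = 5e4)
  m2 <- as.matrix(st2$counts[, -1])
  ra <- sweep(m2, 1, rowSums(m2), "/")
  k <- which.max(mu)
  ratio <- mean(ra[st2$design$group == 1, k]) /
    mean(ra[st2$design$group == 0, k])
  target <- sp$mu1[k] / sp$mu0[k]
  expect_gt(ratio / target, 0.85)
  expect_lt(ratio / target, 1.15)
})

test_that("correlated mixing builds integer clusters with excess within-cluster correlation", {
  set.seed(45)
  mu <- make_baseline(30, 1.5)
  st <- simulate_study(mu, mu, 40)
  mixed <- make_correlated(st$counts, st$design, mu, mu)
  m <- as.matrix(mixed$counts[, -1])
  expect_true(all(m == round(m)))
  expect_equal(as.integer(table(mixed$design$cluster_id)), rep(2L, 20))
  expect_error(make_correlated(st$counts[1:19, ], st$design[1:19, ], mu, mu),
               "divisible")
  # within-cluster count correlation exceeds between-cluster correlation
  set.seed(46)
  big <- simulate_study(mu, mu, 400)
  bigm <- make_correlated(big$counts, big$design, mu, mu)
  m <- as.matrix(bigm$counts[, -1])
  cl <- bigm$design$cluster_id
  ord <- order(cl)
  m <- m[ord, ]; cl <- cl[ord]
  k <- which(colMeans(m > 0) > 0.9)[1]
  a <- m[seq(1, nrow(m), 2), k]
  b <- m[seq(2, nrow(m), 2), k]
  within <- cor(a, b)
  between <- cor(a[-1], b[-length(b)])
  expect_gt(within, between)
})

test_that("meta-experiments are reproducible with shared homogeneous truth", {
  cfg <- sim_config(n_studies = 3, n_samples = c(20, 20, 20),
                    n_features = 92, seed = 99)
  s1 <- simulate_meta_experiment(cfg)
  s2 <- simulate_meta_experiment(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$studies[[2]]$counts, s2$studies[[2]]$counts)
  # round(0.1 * 92) = 9 active, folds in (1, max_fold]
  expect_equal(sum(s1$truth$active), 9)
  act <- s1$truth[s1$truth$active, ]
  expect_true(all(act$fold > 1 & act$fold <= cfg$max_fold))
  expect_equal(act$true_log_effect, act$sign * log(act$fold))
  expect_true(all(s1$truth$true_log_effect[!s1$truth$active] == 0))
  # adding a study leaves earlier studies untouched
  cfg4 <- sim_config(n_studies = 4, n_samples = c(20, 20, 20, 20),
                     n_features = 92, seed = 99)
  s4 <- simulate_meta_experiment(cfg4)
  expect_identical(s4$studies[[1]]$counts, s1$studies[[1]]$counts)
  # correlated variant clusters every study
  cfgc <- sim_config(n_studies = 2, n_samples = c(20, 24), n_features = 40,
                     seed = 7, correlated = TRUE)
  sc <- simulate_meta_experiment(cfgc)
  expect_true(!is.null(sc$studies[[1]]$design$cluster_id))
})
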