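#' Configuration for the multi-study spike-in simulator
#'
#' Bundles and validates the knobs of the synthetic multi-study generator.
#' The defaults reproduce the genus-level, large-sample benchmark
#' condition: five studies of 100..180 samples, 92 features, 10% active
#' features with fold changes drawn from Uniform(1, 5), balanced effect
#' directions and even sequencing depths.
#'
#' @param n_studies Number of studies L.
#' @param n_samples Integer vector of per-study sample sizes (all even; two
#'   equal groups per study).
#' @param n_features Number of microbial features K.
#' @param prop_active Proportion of active (truly AA-differential) features,
#'   in (0, 0.5).
#' @param max_fold Upper bound of the Uniform(1, max_fold) fold-change
#'   distribution for active features (> 1).
#' @param effect_direction `"balanced"` (signs +/- with probability 1/2) or
#'   `"positive"` (all positive).
#' @param depth_scheme `"even"` (depths drawn from one pool) or `"uneven"`
#'   (depths additionally doubled in one randomly picked group).
#' @param depth_meanlog,depth_sdlog,depth_min Log-normal depth pool
#'   parameters and hard floor (defaults 9.5, 0.5, 2000 reads; the floor
#'   mirrors the usual practice of discarding ultra-shallow samples).
#' @param abundance_threshold Mean-proportion cut defining the "relatively
#'   abundant" stratum from which half of the active features are drawn
#'   (default 1e-3).
#' @param baseline_sdlog Standard deviation of the log-normal baseline
#'   log-abundances (default 2.5; gives a few dominant features and a long
#'   tail of rare ones).
#' @param study_sdlog Standard deviation of the study-level log-normal
#'   perturbation around the shared abundance profile (default 1). Studies
#'   of the same ecosystem share the overall profile shape; this controls
#'   how much their mean proportion vectors deviate from it (0 = identical
#'   baselines; with the defaults the cross-study correlation of
#'   log-abundances is about 0.86).
#' @param dirichlet_scale Dirichlet concentration scale for per-sample
#'   proportion overdispersion (default 50; smaller = noisier).
#' @param correlated If `TRUE`, samples are mixed pairwise into clusters of
#'   two correlated members each.
#' @param seed Master seed; the whole experiment is reproducible from the
#'   config alone.
#' @return A validated list of class `palm_sim_config`.
#' @export
sim_config <- function(n_studies = 5L,
                       n_samples = c(100L, 120L, 140L, 160L, 180L),
                       n_features = 92L,
                       prop_active = 0.1,
                       max_fold = 5,
                       effect_direction = c("balanced", "positive"),
                       depth_scheme = c("even", "uneven"),
                       depth_meanlog = 9.5,
                       depth_sdlog = 0.5,
                       depth_min = 2000,
                       abundance_threshold = 1e-3,
                       baseline_sdlog = 2.5,
                       study_sdlog = 1,
                       dirichlet_scale = 50,
                       correlated = FALSE,
                       seed = 1L) {
  effect_direction <- match.arg(effect_direction)
  depth_scheme <- match.arg(depth_scheme)
  if (length(n_samples) == 1) n_samples <- rep(n_samples, n_studies)
  if (length(n_samples) != n_studies) {
    abort("`n_samples` must have one entry per study.")
  }
  if (any(n_samples %% 2 != 0)) abort("all `n_samples` must be even.")
  if (prop_active <= 0 || prop_active >= 0.5) {
    abort("`prop_active` must lie in (0, 0.5).")
  }
  if (max_fold <= 1) abort("`max_fold` must exceed 1.")
  if (abundance_threshold <= 0 || abundance_threshold >= 1) {
    abort("`abundance_threshold` must lie in (0, 1).")
  }
  structure(
    list(n_studies = as.integer(n_studies),
         n_samples = as.integer(n_samples),
         n_features = as.integer(n_features), prop_active = prop_active,
         max_fold = max_fold, effect_direction = effect_direction,
         depth_scheme = depth_scheme, depth_meanlog = depth_meanlog,
         depth_sdlog = depth_sdlog, depth_min = depth_min,
         abundance_threshold = abundance_threshold,
         baseline_sdlog = baseline_sdlog, study_sdlog = study_sdlog,
         dirichlet_scale = dirichlet_scale,
         correlated = isTRUE(correlated), seed = as.integer(seed)),
    class = "palm_sim_config"
  )
}

#' Draw a baseline mean-proportion vector
#'
#' Normalised exp of i.i.d. normal(0, sdlog^2) log-abundances: a few
#' abundant features and a long tail of numerous low-abundance ones, the
#' typical shape of taxonomic profiles. At the default sdlog = 2.5 and
#' K around 400, typically ~5-15% of features exceed the 1e-3
#' mean-proportion cut. Uses the current RNG state.
#'
#' @param n_features K (>= 2).
#' @param baseline_sdlog Spread of log-abundances.
#' @return Proportion vector summing to 1.
#' @export
make_baseline <- function(n_features, baseline_sdlog = 2.5) {
  if (n_features < 2) abort("need at least 2 features.")
  w <- exp(rnorm(n_features, 0, baseline_sdlog))
  w / sum(w)
}

#' Choose active (truly differential) features
#'
#' Selects `round(prop_active * K)` active features: half (rounded down)
#' uniformly from the "relatively abundant" stratum (mean proportion >=
#' `abundance_threshold`), the rest from the complement. Signs are all
#' positive or i.i.d. +/- depending on the direction scheme.
#'
#' @param mu Mean proportion vector (averaged over studies when the active
#'   set is shared).
#' @param prop_active Active proportion.
#' @param abundance_threshold Stratum cut.
#' @param effect_direction `"balanced"` or `"positive"`.
#' @return Tibble with columns `feature` (index), `abundant`, `sign`.
#' @export
choose_active <- function(mu, prop_active, abundance_threshold = 1e-3,
                          effect_direction = c("balanced", "positive")) {
  effect_direction <- match.arg(effect_direction)
  k <- length(mu)
  m <- round(prop_active * k)
  n_ab <- m %/% 2L
  n_rare <- m - n_ab
  abundant <- which(mu >= abundance_threshold)
  rare <- which(mu < abundance_threshold)
  if (length(abundant) < n_ab) {
    abort(sprintf("abundant stratum has %d features, need %d.",
                  length(abundant), n_ab))
  }
  if (length(rare) < n_rare) {
    abort(sprintf("rare stratum has %d features, need %d.",
                  length(rare), n_rare))
  }
  idx <- c(sample(abundant, n_ab), sample(rare, n_rare))
  sign <- if (effect_direction == "positive") rep(1, m)
          else ifelse(rbinom(m, 1, 0.5) == 1, 1, -1)
  tibble::tibble(feature = idx, abundant = idx %in% abundant, sign = sign)
}

#' Spike differential effects into a baseline
#'
#' Starting from `mu1 = mu0 = mu`, multiplies the proportions of
#' positive-effect active features by their fold in `mu1` and those of
#' negative-effect features by their fold in `mu0`, then renormalises both
#' vectors to sum to 1. Renormalisation shifts the relative abundances of
#' *all* features, but only the active features are truly AA-differential:
#' the ground-truth AA log-effect is `sign * log(fold)` for active
#' features and exactly 0 otherwise.
#'
#' @param mu Baseline proportion vector.
#' @param active Integer indices of active features.
#' @param folds Fold changes in (1, max_fold], one per active feature.
#' @param signs +1 / -1 per active feature.
#' @return List with `mu0`, `mu1` (each summing to 1) and the length-K
#'   `true_log_effect` vector.
#' @export
spike_in <- function(mu, active, folds, signs) {
  stopifnot(length(active) == length(folds),
            length(active) == length(signs))
  mu0 <- mu1 <- mu
  pos <- signs > 0
  mu1[active[pos]] <- mu1[active[pos]] * folds[pos]
  mu0[active[!pos]] <- mu0[active[!pos]] * folds[!pos]
  truth <- numeric(length(mu))
  truth[active] <- signs * log(folds)
  list(mu0 = mu0 / sum(mu0), mu1 = mu1 / sum(mu1), true_log_effect = truth)
}

draw_depths <- function(n, meanlog, sdlog, minimum) {
  pmax(round(exp(rnorm(n, meanlog, sdlog))), minimum)
}

dirichlet_multinomial <- function(depth, mu, scale) {
  g <- rgamma(length(mu), shape = scale * mu, rate = 1)
  if (sum(g) == 0) g[which.max(mu)] <- 1   # degenerate guard
  drop(rmultinom(1, size = depth, prob = g / sum(g)))
}

#' Generate counts for one two-group study
#'
#' Draws n/2 samples per group (X = 0 and X = 1). Each sample's proportion
#' vector is Dirichlet(`dirichlet_scale * mu_g`) — introducing the
#' sample-to-sample overdispersion seen in real profiles — and counts are
#' multinomial at the sample's sequencing depth. Depths come from a
#' log-normal pool with a hard floor; under the `"uneven"` scheme the
#' depths of one randomly picked group are additionally doubled.
#'
#' @param mu0,mu1 Group mean proportion vectors (from [spike_in()]).
#' @param n Total samples (even).
#' @param depth_scheme `"even"` or `"uneven"`.
#' @param dirichlet_scale Overdispersion scale.
#' @param depth_meanlog,depth_sdlog,depth_min Depth pool parameters.
#' @param study_id Label used in sample ids.
#' @return List with `counts` (count tibble) and `design` (tibble with
#'   `sample_id`, `group`).
#' @export
simulate_study <- function(mu0, mu1, n, depth_scheme = c("even", "uneven"),
                           dirichlet_scale = 50, depth_meanlog = 9.5,
                           depth_sdlog = 0.5, depth_min = 2000,
                           study_id = "study1") {
  depth_scheme <- match.arg(depth_scheme)
  if (n %% 2 != 0) abort("`n` must be even (two equal groups).")
  k <- length(mu0)
  group <- rep(c(0L, 1L), each = n / 2)
  depths <- draw_depths(n, depth_meanlog, depth_sdlog, depth_min)
  if (depth_scheme == "uneven") {
    boosted <- sample(c(0L, 1L), 1)
    depths[group == boosted] <- 2 * depths[group == boosted]
  }
  counts <- t(vapply(seq_len(n), function(i) {
    mu_g <- if (group[i] == 1L) mu1 else mu0
    dirichlet_multinomial(depths[i], mu_g, dirichlet_scale)
  }, numeric(k)))
  rownames(counts) <- sprintf("%s_s%03d", study_id, seq_len(n))
  colnames(counts) <- sprintf("feature%03d", seq_len(k))
  list(counts = count_tibble(counts),
       design = tibble::tibble(sample_id = rownames(counts), group = group))
}

#' Mix samples into correlated clusters
#'
#' Pairs samples within each group into clusters of two and induces
#' within-cluster correlation by mixing each member with a shared extra
#' independent draw from the same group: member counts become
#' `round((Y_star + Y) / 2)` elementwise (round half to even, keeping
#' counts integral). Depths are recomputed as row sums of the mixed
#' counts. Requires group sizes divisible by two.
#'
#' @param counts,design A study as returned by [simulate_study()].
#' @param mu0,mu1 The group mean proportion vectors used to generate the
#'   study (needed to draw the shared extra samples).
#' @inheritParams simulate_study
#' @return List with mixed `counts` and `design` gaining a `cluster_id`
#'   column.
#' @export
make_correlated <- function(counts, design, mu0, mu1,
                            dirichlet_scale = 50, depth_meanlog = 9.5,
                            depth_sdlog = 0.5, depth_min = 2000) {
  m <- count_matrix(counts)
  group <- design$group
  cluster_id <- character(nrow(m))
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) %% 2 != 0) {
      abort("group size must be divisible by 2 to form clusters.")
    }
    n_cl <- length(idx) / 2
    extra_depths <- draw_depths(n_cl, depth_meanlog, depth_sdlog, depth_min)
    mu_g <- if (g == 1L) mu1 else mu0
    for (cl in seq_len(n_cl)) {
      members <- idx[c(2 * cl - 1, 2 * cl)]
      y_star <- dirichlet_multinomial(extra_depths[cl], mu_g,
                                      dirichlet_scale)
      m[members[1], ] <- round((y_star + m[members[1], ]) / 2)
      m[members[2], ] <- round((y_star + m[members[2], ]) / 2)
      cluster_id[members] <- sprintf("g%s_c%03d", g, cl)
    }
  }
  design$cluster_id <- cluster_id
  list(counts = count_tibble(m), design = design)
}

#' Simulate a full multi-study spike-in experiment
#'
#' Generates per-study baselines (heterogeneous across studies), chooses
#' one active set with signs and Uniform(1, max_fold) folds *shared by all
#' studies* (homogeneous true effects) based on the mean baseline, spikes
#' the effects into every study's baseline, and draws counts per study;
#' optionally mixes samples into correlated clusters. Per-study RNG
#' streams are derived from the master seed by fixed offsets, so adding a
#' study never perturbs earlier ones; the whole experiment is reproducible
#' from the config alone.
#'
#' @param config A [sim_config()].
#' @return List of class `palm_sim` with `studies` (each `counts`,
#'   `design`, `study_id`), `truth` (tibble: `feature_id`, `active`,
#'   `sign`, `fold`, `true_log_effect`) and the `config`.
#' @export
simulate_meta_experiment <- function(config) {
  stopifnot(inherits(config, "palm_sim_config"))
  k <- config$n_features
  # shared log-abundance profile: studies of one ecosystem see correlated,
  # not independent, taxon profiles; study_sdlog sets the deviation
  set.seed(config$seed)
  shared_log <- rnorm(k, 0, config$baseline_sdlog)
  baselines <- lapply(seq_len(config$n_studies), function(l) {
    set.seed((config$seed + 7919L * l) %% .Machine$integer.max)
    w <- exp(shared_log + rnorm(k, 0, config$study_sdlog))
    w / sum(w)
  })
  # reference profile for the active-set strata: the shared profile, so the
  # chosen set does not depend on how many studies are simulated
  mu_ref <- exp(shared_log) / sum(exp(shared_log))

  set.seed((config$seed + 500009L) %% .Machine$integer.max)
  act <- choose_active(mu_ref, config$prop_active,
                       config$abundance_threshold, config$effect_direction)
  folds <- runif(nrow(act), 1, config$max_fold)
  truth <- tibble::tibble(
    feature_id = sprintf("feature%03d", seq_len(k)),
    active = seq_len(k) %in% act$feature,
    sign = 0, fold = NA_real_, true_log_effect = 0
  )
  truth$sign[act$feature] <- act$sign
  truth$fold[act$feature] <- folds
  truth$true_log_effect[act$feature] <- act$sign * log(folds)

  studies <- lapply(seq_len(config$n_studies), function(l) {
    sp <- spike_in(baselines[[l]], act$feature, folds, act$sign)
    set.seed((config$seed + 104729L * l) %% .Machine$integer.max)
    study_id <- sprintf("study%d", l)
    st <- simulate_study(sp$mu0, sp$mu1, config$n_samples[l],
                         depth_scheme = config$depth_scheme,
                         dirichlet_scale = config$dirichlet_scale,
                         depth_meanlog = config$depth_meanlog,
                         depth_sdlog = config$depth_sdlog,
                         depth_min = config$depth_min, study_id = study_id)
    if (config$correlated) {
      st <- make_correlated(st$counts, st$design, sp$mu0, sp$mu1,
                            dirichlet_scale = config$dirichlet_scale,
                            depth_meanlog = config$depth_meanlog,
                            depth_sdlog = config$depth_sdlog,
                            depth_min = config$depth_min)
    }
    st$study_id <- study_id
    st
  })
  structure(list(studies = studies, truth = truth, config = config),
            class = "palm_sim")
}

#' @export
print.palm_sim <- function(x, ...) {
  cat("Simulated meta-experiment:", length(x$studies), "studies,",
      x$config$n_features, "features,", sum(x$truth$active),
      "active features\n")
  invisible(x)
}
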