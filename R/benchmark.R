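#' Benchmark FDR, power and heterogeneity on simulated meta-experiments
#'
#' Repeats the full pipeline — simulate a multi-study experiment, compute
#' per-study AA summary statistics, meta-analyse, apply BH — and scores
#' discoveries against the simulator's ground truth. Per replicate it
#' records the false-discovery proportion (false discoveries over
#' discoveries, 0 when nothing is discovered), power (discovered fraction
#' of active features) and the fraction of features flagged heterogeneous
#' (Cochran's Q BH q-value below `het_q_level`; the simulator's effects
#' are homogeneous across studies, so this should stay near zero).
#'
#' Before analysis, features are filtered at `prev_filter` prevalence
#' computed across all samples of all studies, mirroring the standard
#' practice of assembling the cross-study analysis set from reasonably
#' prevalent features; the filter is external to the per-study model and
#' sequencing-depth offsets are always taken from the unfiltered tables.
#' Set `prev_filter = 0` to analyse every simulated feature including
#' arbitrarily rare ones.
#'
#' @param config A [sim_config()]; replicate r uses master seed
#'   `config$seed + r - 1`.
#' @param n_replicates Number of simulation replicates.
#' @param fdr_level Nominal BH level (default 0.05).
#' @param het_q_level Heterogeneity q-value threshold (default 0.1).
#' @param prev_filter Cross-study prevalence cut defining the analysis
#'   set (default 0.2).
#' @return Tibble with one row per replicate: `replicate`, `fdp`,
#'   `power`, `n_discoveries`, `prop_heterogeneous`, `n_features_tested`.
#' @export
benchmark_fdr <- function(config, n_replicates = 50L, fdr_level = 0.05,
                          het_q_level = 0.1, prev_filter = 0.2) {
  stopifnot(inherits(config, "palm_sim_config"))
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_meta_experiment(cfg)
    mats <- lapply(sim$studies, function(st) count_matrix(st$counts))
    keep <- if (prev_filter > 0) {
      pooled <- do.call(rbind, mats)
      colnames(pooled)[colMeans(pooled > 0) >= prev_filter]
    } else {
      colnames(mats[[1]])
    }
    stats <- purrr::map2(sim$studies, mats, function(st, m) {
      md <- st$design
      md$total_depth <- rowSums(m)   # offsets from the unfiltered table
      suppressMessages(palm_fit(
        m[, keep, drop = FALSE], md, covariate = "group",
        cluster = if ("cluster_id" %in% names(md)) "cluster_id",
        depth = "total_depth", study_id = st$study_id
      ))
    })
    meta <- palm_meta(stats, fdr_level = fdr_level,
                      het_q_level = het_q_level)
    scored <- dplyr::left_join(tidy(meta), sim$truth, by = "feature_id")
    disc <- sum(scored$significant)
    fd <- sum(scored$significant & !scored$active)
    tibble::tibble(
      replicate = r,
      fdp = if (disc > 0) fd / disc else 0,
      power = sum(scored$significant & scored$active) /
        max(sum(sim$truth$active), 1L),
      n_discoveries = disc,
      prop_heterogeneous = mean(scored$heterogeneous, na.rm = TRUE),
      n_features_tested = nrow(scored)
    )
  })
}
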