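---
title: "Recovering absolute-abundance associations from relative-abundance counts: model, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering absolute-abundance associations from relative-abundance counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palm)
```

## Why relative-abundance effects are not the effects of interest

Let $W_{ik}$ be the latent absolute abundance (AA) of microbial feature
$k$ in sample $i$, $O_i = \sum_k W_{ik}$ the total load, $X_i$ the
covariate of interest, $N_i$ the sequencing depth and $Y_{ik}$ the read
count. Modelling $E[W_{ik} \mid X_i] = \exp(\beta_{0k} + \beta_k X_i)$
and passing through the multinomial sampling of sequencing gives a
marginal relative-abundance (RA) mean of log-linear form

$$E[Y_{ik} \mid X_i] = N_i \exp(\beta_{0k}^\dagger + \beta_k^* X_i),
  \qquad \beta_k^* = \beta_k - \beta_O ,$$

where feature-specific measurement biases and the load factor are
absorbed into the intercept, and $\beta_O$ — the association of total
load with $X$ — shifts *every* feature's RA effect by the same amount.
Testing $\beta_k^* = 0$ therefore answers the wrong question whenever the
load responds to the covariate. The package estimates $\beta_k^*$ per
feature, estimates the common shift, and reports AA-level statistics
$\hat\beta_k$ with calibrated variances that are poolable across studies.

This derivation relies on a mean-independence condition (the residual
load factor $E[e^{-\bar O_i}\mid X_i]$ constant in $X$), which holds
approximately when $K$ is large, no single feature dominates the
ecosystem, and cross-feature dependence is not pervasive.

## Per-study estimation

**Null model.** For each feature one quasi-Poisson model with variance
$\phi\,\mu$ is fitted under the null (intercept plus confounders, never
the covariate of interest), with offset $\log N_i$, using the
Firth-penalised quasi-score

$$\sum_i \left(Y_{ik} - \mu_{ik} + \tfrac{1}{2}h_{ik}\right)\tilde x_i = 0,$$

where $h_{ik}$ is the leverage (diagonal of the weighted hat matrix) of
the null design. The penalty bias-reduces the estimates and keeps
boundary cases finite: with an intercept-only design the fixed point is
$\sum_i \mu_i = \sum_i Y_i + \tfrac12$, so an all-zero feature still has
a finite fitted intercept. The dispersion $\phi$ cancels from the score
equations and is never estimated — all uncertainty is carried by the
sandwich estimator below, which is what makes the approach robust to the
strong overdispersion of real count profiles.

*Numerical scheme.* Newton iteration on the quasi-information with step
halving; starting value $\beta_0 = \log\{(\sum Y + q_0/2)/\sum N\}$
(exact for intercept-only models, so degenerate features converge in one
step), convergence at maximum absolute score $< 10^{-8}$ or relative
coefficient change $< 10^{-10}$, at most 100 iterations. Rank-deficient
designs error; non-convergent features are excluded from the study's
summary table (they drop out of that feature's study set at
meta-analysis, exactly like features that were never observed).

**Score-statistic effect.** With the null fit $\tilde\theta_k$ fixed,
the effect of any covariate is the one-step estimator
$\hat\beta_k^* = \mathcal I_1^{-1} S_1(\tilde\theta_k)$, where $S_1$ is
the covariate block of the quasi-score and $\mathcal I_1 = \mathcal
I_{11} - \mathcal I_{10}\mathcal I_{00}^{-1}\mathcal I_{01}$ the
effective information. This is the Taylor expansion of the quasi-score
at the null, the same device used in large-scale association scans:
thousands of covariates can be scanned against one set of null fits.
The leverage inside the score is taken from the null design, preserving
the covariate-independence of the fit; the alternative convention
(leverages from the full design evaluated at the null fit) differs by
$O(1/n)$ on toy cases, which the test suite documents. One consequence
of the one-step form is mild shrinkage of very large effects (second
order in $\beta$); it costs some power at extreme fold changes but does
not affect calibration under the null.

**Sandwich variance.** $V_k^* = \mathcal I_1^{-1}\left(\sum_i
U_i^2\right)\mathcal I_1^{-1}$ with $U_i = r_i\,(x_i - \tilde
x_i^\top\mathcal I_{00}^{-1}\mathcal I_{01})$ and $r_i$ the
Firth-adjusted residual. For correlated samples (clusters), per-sample
contributions are summed within clusters before squaring; with singleton
clusters this reduces exactly to the independent form. No small-sample
degrees-of-freedom correction is applied for very few clusters
(fewer than ~10); variances in that regime should be read with care.
All-zero features make every $r_i$ vanish identically (the intercept-only
fixed point implies $h_i/2 = \mu_i$ when $\sum Y = 0$), so unobserved
features are excluded from a study rather than reported with a degenerate
zero variance; a guard also excludes any feature whose sandwich collapses
numerically.

## Compositional correction and variance calibration

Under the sparse-signal assumption — most features have no AA effect —
the shift $-\beta_O$ is estimated by the median of the per-feature RA
effects, and

$$\hat\beta_k = \hat\beta_k^* - \mathrm{median}_j\{\hat\beta_j^*\},
\qquad
V_k = V_k^* + \frac{K}{4\left(\sum_j (2\pi V_j^*)^{-1/2}\right)^2}.$$

The printed form of the calibration term is ambiguous in isolation; the
reading adopted here is the only one that reduces to $\pi V/(2K)$ — the
classical asymptotic variance of the median of $K$ independent normal
draws — in the equal-variance case, and Monte-Carlo checks in the test
suite confirm it within 5% for $K \in \{21, 92, 401\}$. The term is
common to all features of a study, strictly positive, and decays like
$1/K$. The correction is computed per (study, covariate) over exactly the
features with valid RA summaries in that study; below 20 such features a
warning flags that the sparsity assumption is fragile (the threshold is
configurable via `k_floor`). With even feature counts the median is the
midpoint of the central order statistics. When a large fraction of
features is differential in one direction (~40%), the median itself is
biased and AA-level results degrade; this is an intrinsic limit of the
identification strategy, not of the implementation.

## Meta-analysis

Per feature, studies where the feature was observed contribute
$\hat\beta_{k\ell}, V_{k\ell}$ to a fixed-effect inverse-variance pool;
$Q = \hat\beta_{meta}^2/V_{meta}$ is referred to $\chi^2_1$, and
between-study heterogeneity is assessed by Cochran's Q on $L-1$ degrees
of freedom. BH correction runs over features, separately for association
and heterogeneity p-values (and per covariate when scanning). Discoveries
are `q_value <= fdr_level` (0.05 default); heterogeneous features are
`het_q < het_q_level` (0.1 default; the boundary conventions are
immaterial at double precision but fixed here). Only the fixed-effect
model is offered: the summary statistics are designed to be homogeneous
across studies, and the heterogeneity test is the diagnostic for when
they are not.

## The simulator: what it emulates and what it does not

The generator reproduces the statistical structure of a spike-in
evaluation protocol without any dependence on real template data:

* **Abundance profiles.** A shared log-abundance profile $a_k \sim
  N(0, \sigma^2)$, $\sigma = 2.5$, gives the heavy-tailed shape of
  taxonomic profiles — a few dominant features, a long tail of rare
  ones, and typically ~5–15% of features above the $10^{-3}$
  mean-proportion cut at $K \approx 400$. Each study perturbs the shared
  profile with its own $N(0, \tau^2)$ noise, $\tau = 1$ by default
  (cross-study correlation of log-abundances $\approx 0.86$), then
  normalises. Studies of the same ecosystem see correlated — not
  independent — profiles; fully independent baselines would make a
  feature's abundance unrelated across studies, which no real
  multi-study collection resembles and which would make homogeneous
  effect pooling meaningless.
* **Active features.** `round(0.1·K)` active features by default, half
  (rounded down) from the relatively-abundant stratum (mean proportion
  $\ge 10^{-3}$ on the shared profile, so the chosen set does not depend
  on the number of studies), half from the complement; signs balanced or
  all-positive; folds $\sim$ Uniform(1, 5). Spiking multiplies the
  affected group's mean proportions and renormalises — which shifts the
  RA of *all* features, while the AA ground truth of inactive features
  remains exactly zero. The active set, signs and folds are shared by
  all studies (homogeneous effects).
* **Counts.** Per-sample proportions are Dirichlet with concentration
  $\phi_d\,\mu_g$ ($\phi_d = 50$), counts multinomial at a log-normal
  depth (mean-log 9.5, sd-log 0.5, floor 2000 reads — mirroring the
  practice of discarding ultra-shallow samples). The Dirichlet scale is a
  deliberate simplification: it reproduces realistic overdispersion and
  zero-inflation but not the feature-by-feature correlation structure a
  template-based simulator would copy from real data, so benchmark
  numbers are comparable in kind, not guaranteed to transfer
  quantitatively. Under the uneven-depth scheme one randomly chosen
  group's depths are doubled.
* **Correlated samples.** Pairs within a group form clusters; each
  member is mixed with a shared extra draw from the same group,
  `round((Y* + Y)/2)` (round-half-to-even keeps counts integral), and
  depths are recomputed.
* **Reproducibility.** Per-study RNG streams are derived from the master
  seed by fixed offsets, so the whole experiment is a pure function of
  its configuration and adding a study never perturbs earlier ones.

## Benchmark protocol

`benchmark_fdr()` runs the full pipeline over replicated experiments and
scores discoveries against the generator's truth. Two protocol details
matter:

* Features are filtered at **20% prevalence across all samples of all
  studies** before analysis. Multi-study analyses assemble their feature
  set this way, and a template-based spike-in inherits the filter through
  its templates; a self-contained generator must apply it explicitly,
  otherwise the benchmark is dominated by ultra-rare features that a real
  analysis set would never contain. Setting `prev_filter = 0` exposes
  that regime deliberately.
* Sequencing-depth offsets always come from the **unfiltered** tables,
  so filtering never changes a sample's depth.

The default experiment — five studies of 100–180 samples, $K = 92$,
balanced directions, even depths, 10% active, folds Uniform(1, 5), 50
replicates — yields an empirical FDR at the nominal 0.05 BH level of
about 0.04–0.06 depending on seed, essentially no heterogeneity flags
(homogeneous truth), and power around 0.5 against the mostly-moderate
spiked folds. The acceptance script reports exactly this quantity.

## Problem sizes and numerical choices in the checks

The test suite verifies, among others: the intercept-only closed form to
$10^{-10}$ over 1000 random instances including all-zero features;
first-order agreement of the score estimator with an independently
located quasi-score root on 100 instances of $n \le 8$ (bound
$\tfrac12\beta^2$, the root found by derivative-free minimisation of the
squared score with the Firth term held at the null fit — the function
whose expansion defines the estimator); sandwich calibration within
[0.85, 1.15] of the empirical variance over 500 replicates at
$n = 2000$ under dispersion 3; exact singleton-cluster reduction;
median-calibration agreement with Monte-Carlo within 5%; unbiased
recovery of spiked effects at $n = 200$ (within 2 Monte-Carlo SE);
KS-uniformity of meta p-values under a global null over 2000
feature-replicates; and the 50-replicate FDR/heterogeneity benchmark.
Sizes were chosen so the full suite completes in a few minutes while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The median-based identification fails gracefully but measurably as the
  differential fraction grows one-sided (see above); 40% one-directional
  signal is beyond its design envelope.
* The one-step score estimator trades a little power at very large
  effects for the single-fit covariate-scan speed.
* No small-cluster correction for the clustered sandwich.
* The simulator's Dirichlet overdispersion is a declared surrogate for
  template-learned correlation structure; distribution-level realism
  (e.g. phylogenetically structured co-occurrence) is out of scope.
* Prevalence filtering conventions (cross-study vs within-study) are both
  exposed and neither privileged; results at low prevalence depend on the
  choice, and the per-study exclusion of unobserved features means the
  analysed study set can differ across features by design.
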