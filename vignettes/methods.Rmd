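---
title: "Environment-dependent diversification inference with chronodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment-dependent diversification inference with chronodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chronodiv asks a single scientific question of a time-calibrated phylogeny:
did speciation track an environmental driver — typically a paleotemperature
proxy such as benthic δ¹⁸O — rather than simply time? It answers with three
complementary lines of evidence, each implemented and validated against the
others on fully synthetic data:

1. maximum-likelihood birth–death models whose speciation (and optionally
   extinction) rate is constant, exponential in time, or exponential in an
   environmental covariate, compared by AICc and summarised as an evidence
   ratio between the temperature and time model families;
2. detrended cross-correlation analysis (DCCA) between posterior
   rate-through-time curves and the proxy;
3. phylogenetically corrected tip-rate association tests (equal-splits/
   Es-Sim, structured rate permutations, the Fritz–Purvis D statistic) and
   bioregion-level summaries.

## The birth–death model and its likelihood

Ages `t` are measured in My before present, tips at 0, crown node at
`t_c`. Rates are per lineage per My. The rate forms are
λ(t) = λ₀e^{βt} (time family) and λ(t) = λ₀e^{αT(t)} (environment
family), where `T(t)` is the covariate after Tukey smoothing and linear
interpolation — exactly the preprocessing the DCCA stage applies, so both
analyses see the same curve. Extinction is either absent, constant, or
exponential in the same driver. Linear rate dependencies are deliberately
not offered: they routinely go negative over deep time and are biased
against environment-dependent models.

With `f` the sampling fraction, `r(t) = ∫₀ᵗ(λ−μ)du` and
`g(t) = 1/f + ∫₀ᵗ λe^{r}ds`, the reconstructed-process likelihood of the
crown tree is

```
log L = Σ_nodes log λ(t_i) + Σ_edges log Ψ(s, t) + n log f
Ψ(s,t) = e^{r(t)−r(s)} (g(s)/g(t))²,   Φ(t) = 1 − e^{r(t)}/g(t)
```

optionally minus `2 log(1 − Φ(t_c))` to condition on both crown lineages
surviving to be sampled. Because Ψ is multiplicative along root-to-tip
paths, the edge sum telescopes onto the node ages; for constant rates the
whole expression collapses to the classical closed form, which the test
suite verifies to 10⁻⁶ on simulated trees (in practice agreement is at
machine precision).

### Numerics

The integrals are accumulated on a dense age grid (default `n_grid = 2000`
points from 0 to the crown age) into which the node ages are inserted, so
no interpolation error enters at branching times. Segments are integrated
log-linearly (geometric trapezoid), which is *exact* for constant and
exponential-in-time rates and third-order accurate otherwise; doubling the
grid moves the log-likelihood by far less than 10⁻⁴ (tested). Parameter
values that overflow `e^{r}` raise an error rather than propagating NaN.

Fitting uses Nelder–Mead (Brent for one-parameter models) from five
deterministic starts fanned around a Yule-style initial guess; base rates
are optimized on the log scale and slopes are restricted to [−10, 10].
Refitting the same tree therefore reproduces estimates bit-for-bit.

### Conditioning: a deliberate default

The package defaults to **no survival conditioning for the six-model
comparison** (`fit_bd_modelset(conditioning = "none")`), while single-model
fits default to crown-survival conditioning. This departs from the common
habit of always conditioning, for a reason we found empirically and can
reproduce on any tree, including constant-rate trees simulated with
`ape::rphylo`: under crown-survival conditioning, the exponential-extinction
models admit a *subcritical ridge* — μ(t) > λ(t) with both growing into the
past — whose likelihood advantage (5–10 log-units) comes almost entirely
from the conditioning denominator `−2 log(1−Φ)`: parameters that make
survival improbable are rewarded by the division. Without conditioning the
same models gain only ordinary overfitting amounts (≲2.5 log-units), which
the AICc penalty absorbs, and model selection behaves as expected. The
conditioned likelihood remains available and is exactly checked against the
closed form; it is the *comparison across families* that should not use it.

### AICc conventions

`AICc = −2 log L + 2k + 2k(k+1)/(n−k−1)` with `n` the number of tips (the
convention of comparable ML diversification software; whether branching
times would be the better `n` is unresolved in the literature). Weights are
computed jointly across all six models and the evidence ratio is
`Σω(temperature) / Σω(time)`; values above 1 favor the covariate.

## DCCA

`dcca_coefficient` implements the Podobnik–Stanley coefficient at a single
scale: both series are integrated to profiles, every overlapping window of
`box_size` points is detrended by an OLS line, and the box-averaged residual
covariance is normalised by the residual variances. The default scale is
`⌊N/4⌋` with order-1 detrending — a mid-range choice, exposed as an
argument, since no canonical scale exists. DCCA is used instead of plain
Pearson correlation because both the rate curves and the proxies are
strongly autocorrelated, nonstationary series.

`ensemble_climate_test` enforces the pipeline order — smooth the proxy,
interpolate it to the ensemble grid, then correlate — and summarises the
per-posterior-sample coefficients with their mean and a one-sample Wilcoxon
signed-rank test against zero. Two caveats are deliberate: the phrase
"rank-sum" in parts of the literature names a two-sample test, so that
variant is available via `rank_sum = TRUE`; and posterior draws are
correlated, so the p-value is descriptive, not strictly calibrated (the
test suite checks its type-I behaviour on *independent* rows only).

## Tip-rate tests

* `es_statistic`: equal-splits `ES` (tip edge weight 1, halving toward the
  root; a stem edge, when present, is the last segment) and `DR = 1/ES`.
* `essim_test`: Pearson correlation of a continuous trait with `log(DR)`,
  judged against the same statistic on Brownian simulations of the trait
  with the ML σ² (closed-form GLS estimate on the tree covariance).
* `strapp_test`: rates enter at regime resolution (each tip carries its
  regime's mean tip rate) and the regimes' rate values are permuted among
  regimes. This preserves the block structure that defeats phylogenetic
  pseudoreplication while requiring no Bayesian shift-configuration
  machinery; with a single regime the statistic is exactly invariant and
  p = 1. Spearman, Mann–Whitney and Kruskal–Wallis statistics cover
  continuous, binary and categorical traits.
* `d_statistic`: Fritz–Purvis D with nodal values estimated by post-order
  daughter averaging; the d sum is scaled between its mean under random
  shuffling (D = 1) and under threshold-discretised Brownian motion at the
  observed prevalence (D = 0). Exact-count thresholding keeps the
  prevalence fixed across simulations.
* All permutation p-values use the small-sample estimator
  `(1 + #exceedances)/(1 + n)`, so p is never exactly zero.
* `classify_tropical` applies strict-majority rules: a species is tropical
  when *more than half* of its localities fall within ±23.5° latitude
  (boundary inside) or above 18 °C; exactly half is nontropical.

## Bioregions

Endemics are species assigned to exactly one region. Grid summaries use
equal-angle lon/lat cells scaled to a target equatorial area (default
200 km²) — a deliberately simple geometry, configurable, since published
map-grid descriptions are rarely reproducible to the cell. Per-region
rate-through-time curves are compared with Pearson correlations, and
rate-versus-temperature relationships over a recent window (default 10 My)
are summarised by least-squares fits of `rate = a·e^{bT}` (Levenberg–
Marquardt, log-linear fallback on degenerate surfaces).

## The synthetic scenario: what it emulates, and what not

`simulate_climate` produces a linear trend plus a sinusoid plus Gaussian
noise. The bundled "orchid-like" scenario uses a 65-My span cooling from
4 to 0.5 proxy units with oscillation amplitude 1.5, period 18 My and
noise sd 0.15. The amplitude and period were chosen to match the character
of the real Cenozoic benthic δ¹⁸O record, which departs from any linear
trend by ~1.5 ‰ over >10-My windows (the Eocene–Oligocene step, the
mid-Miocene climatic optimum). This matters scientifically: a nearly
linear covariate makes `exp_env` and `exp_time` observationally equivalent,
and no method could — or should — distinguish them. Identifiability of the
temperature family comes precisely from the covariate's departures from
linearity.

`simulate_bd_tree` runs the forward birth–death process from two crown
lineages with thinning (piecewise bounds recomputed on 1-My windows at
1.1× the maximal total rate), prunes extinct lineages, binomially
subsamples tips with probability `f`, and redraws until the sampled tip
count lands in the accepted window. Pure-birth tip counts match
`2e^{λT}` to Monte-Carlo error and `f`-thinning is exactly binomial on the
realized tips (tested). Crown-survival rejection is on by default for
trees used in fitting and off for branching-process expectation checks,
whose textbook values are unconditional.

Posterior rate ensembles are emulated as the true curve times i.i.d.
mean-one lognormal noise; traits as Brownian motion, threshold-binary
Brownian motion at exact prevalence, or clade-painted rate regimes; and
occurrences as Gaussian scatter around bioregion centroids. What the
generator does **not** emulate: clade-biased (non-uniform) sampling,
rate-shift posteriors with topological uncertainty, spatially structured
sampling bias, and measurement error in the proxy ages. Passing tests on
these synthetics therefore validates the statistical machinery, not the
robustness of any empirical conclusion to those complications.

## Study sizes and expected behaviour

The validation suite runs at desk scale: ~150-tip trees (sampling fraction
0.75, crown age 65 My, accepted tip window 60–400), 50 replicates for
parameter recovery and model selection, 200 replicates for test
calibration, 100 for the D statistic references. At that scale a single
tree's ML estimate of the environmental slope α is noticeably noisy and
tends to sit somewhat closer to zero than the generating value; the
quantity the suite checks is therefore the median over replicate trees.
Users applying the package to a single few-hundred-tip tree should expect
wide uncertainty in α and lean on the evidence ratio and DCCA rather than
the point estimate.

## A worked run

```{r, eval = FALSE}
library(chronodiv)
inputs <- simulate_scenario(orchid_like_scenario(seed = 1))
res <- run_pipeline(inputs, out_dir = "run1", seed = 11)
res$fits$evidence_ratio     # > 1 favors temperature-dependent speciation
res$dcca$mean               # mean DCCA coefficient, rates vs proxy
res$tip_tests$strapp_bioregion$p_value
```

The same computation, reduced to its headline numbers, is what
`scripts/acceptance.R` performs.
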