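# chronodiv

Did a clade's speciation track an environmental driver — global
paleotemperature, CO₂, sea level — rather than time? `chronodiv` implements
the statistical core of that question for time-calibrated phylogenies, for
researchers in macroevolution and historical biogeography:

* **Birth–death model comparison.** Maximum-likelihood fits of the
  reconstructed-process likelihood with incomplete sampling, where the
  speciation rate is λ(t) = λ₀e^{βt} (time-dependent) or
  λ(t) = λ₀e^{αT(t)} (environment-dependent, with T(t) a smoothed,
  interpolated proxy curve), each with no, constant, or exponential
  extinction. Models are compared with AICc, Akaike weights, and the
  **evidence ratio** Σω(temperature models) / Σω(time models).
* **DCCA.** Podobnik–Stanley detrended cross-correlation between every
  posterior rate-through-time curve and a proxy series, with a rank test of
  the coefficient distribution against zero — suited to autocorrelated,
  nonstationary series where Pearson correlation misleads.
* **Tip-rate tests.** Equal-splits (ES/DR) tip rates, the Es-Sim test
  (trait vs log DR against Brownian nulls), STRAPP-style structured rate
  permutations (Spearman / Mann–Whitney / Kruskal–Wallis), the
  Fritz–Purvis D statistic for binary traits, and tropical/temperate
  classification of species from occurrence records.
* **Bioregions.** Endemic filtering, gridded richness and mean tip rate,
  per-region rate-through-time correlation matrices and exponential
  rate-versus-temperature fits.
* **Synthetic data.** Every input the pipeline consumes can be generated:
  birth–death trees under time-varying rates (forward simulation with
  thinning and binomial tip sampling), cooling-curve climate scenarios,
  posterior rate ensembles, Brownian/threshold/regime traits, and
  clustered occurrences. The whole pipeline is testable end to end with no
  external data.

## Worked example

```r
library(chronodiv)

# generate the bundled synthetic study: a 65-My clade under
# temperature-dependent speciation on a cooling proxy curve
inputs <- simulate_scenario(orchid_like_scenario(seed = 1))
inputs$tree
#> Time-calibrated tree: 231 tips, crown age 65 My, sampling fraction f = 0.3

res <- run_pipeline(inputs, seed = 11)
res$fits$table[, c("model", "logL", "k", "dAICc", "weight")]
#>           model      logL k    dAICc     weight
#> 1     env_noext -886.3487 2 0.000000 0.52625965
#> 2  env_constext -886.3487 3 2.053103 0.18852742
#> 3    env_expext -886.3487 4 4.124371 0.06692744
#> 4    time_noext -887.6349 2 2.572387 0.14541638
#> 5 time_constext -887.6349 3 4.625492 0.05209396
#> 6   time_expext -887.5185 4 6.464073 0.02077517
res$fits$evidence_ratio
#> [1] 3.581156
res$dcca
#> DCCA: mean rho = -0.948 over 100 samples (box 32), p = 3.96e-18
```

The evidence ratio (> 1) says the temperature-dependent family carries most
of the AICc weight; `alpha_hat` (the fitted α, here −0.095 per proxy unit
against a generating value of −0.15 — single-tree slope estimates are
noisy, as the vignette discusses) quantifies how strongly speciation
accelerates as the proxy falls; the DCCA mean (−0.95) shows the posterior
rate curves, built around the true temperature-driven curve, are
consistently anticorrelated with the proxy. Tip-rate tests
(`res$tip_tests`) are correctly non-significant here because the synthetic
tip covariates are independent of the rate regimes, and
`res$bioregion` summarises endemic counts, per-region rate–temperature
slopes and the cross-region correlation matrix.

## Conventions

Ages are My before present (tips at 0, increasing into the past); rates
are events/lineage/My; proxies are used on their own scale (δ¹⁸O is an
*inverse* temperature proxy); trees are binary, ultrametric, with a global
sampling fraction `f`. See the methods vignette
(`vignettes/methods.Rmd`) for the likelihood, numerics, the conditioning
default, and what the synthetic generator does and does not emulate.
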