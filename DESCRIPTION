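Package: chronodiv
Title: Environment-Dependent Diversification Inference for Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits time- and environment-dependent birth-death models of
    diversification to ultrametric phylogenies by maximum likelihood and
    compares model families with AICc evidence ratios; correlates posterior
    speciation-rate-through-time ensembles with paleoclimate proxies via
    detrended cross-correlation analysis (DCCA); runs phylogenetically
    corrected tip-rate association tests (equal-splits/Es-Sim, structured
    rate permutations, the D statistic for binary traits); and summarises
    diversification by bioregion. Includes a full synthetic-data generator
    (birth-death tree simulation under time-varying rates with incomplete
    sampling, climate scenarios, posterior rate ensembles, traits and
    occurrences) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
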