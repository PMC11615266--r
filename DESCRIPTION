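Package: sftabund
Title: Space-for-Time Validity Testing with Multispecies Abundance Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether spatial habitat-abundance relationships
    predict temporal change in multispecies point-count communities. Simulates
    two-period landscapes with compositional land cover measured at nested
    buffer radii and detection-thinned counts; selects the optimal scale of
    effect per species and land-cover type by leave-one-out Poisson regression
    (Pearson or Spearman scoring) or boosted-regression-tree relative
    influence; fits hierarchical Bayesian multispecies N-mixture abundance
    models with imperfect detection (a 50-m Scheffe compositional model and a
    multiscale intercept model) via JAGS; and computes the land-cover-only
    counterfactual, per-species percent changes with credible intervals, and a
    five-way classification of space-for-time validity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
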