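Package: biastree
Title: Sampling-Bias Correction and Abundance Estimation for Gridded
    Citizen-Science Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating species abundance from spatially biased,
    presence-only citizen-science records aggregated to a landscape grid.
    Implements the standard sampling-bias corrections for presence-background
    distribution models (systematic, cluster and weighted-distance spatial
    filtering of occurrence records; buffer-restricted and bias-surface-weighted
    pseudo-absence generation), zero-inflated Poisson and negative-binomial
    regression on per-cell pseudo-abundance with count, zero and whole-model
    predictions, Vuong-type non-nested model comparison with AIC/AICc
    correction, k-fold cross-validation with AUC/RMSLE/correlation reporting,
    and calibration of model predictions against effort-adjusted densities from
    stratified field surveys to yield a landscape-wide population total. A
    synthetic-landscape simulator with known truth supports validation of the
    whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
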