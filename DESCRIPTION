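Package: revisit
Title: Foraging-Site Revisitation Analysis for GPS Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects revisited foraging sites in projected GPS trajectories
    (moving-circle recursion with a minimum time-away rule and variance-peak
    radius selection), characterises their environmental non-randomness against
    availability sampled inside an a-LoCoH home range (repeated subsampled
    two-sample Kolmogorov tests), and models revisitation rate as a function of
    environmental covariates (binned quadratic regressions; random-intercept
    mixed models with backward AIC selection, a 2-delta-AIC parsimony rule and
    Nakagawa-Schielzeth R-squared). Ships a seeded synthetic-study generator
    (covariate rasters, water features, NDVI seasonality, hotspot-attraction
    movement) so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    lme4,
    fitdistrplus
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
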