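Package: longewas
Title: Longitudinal Modelling Strategies for Epigenome-Wide Association
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying CpG sites whose DNA methylation
    trajectories differ by an exposure across repeated measures. Provides
    fast many-outcome linear regression with cluster-robust (sandwich)
    standard errors, per-CpG linear mixed models with a random intercept
    or a random intercept and slope, cross-sectional EWAS at each
    time-point with baseline / any-time-point / all-time-points hit
    selection, a simulator of methylation trajectories under six
    exposure-effect scenarios, and an evaluation harness computing power,
    Type I error and relative bias across strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
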