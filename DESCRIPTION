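Package: tempmort
Title: Two-Stage Distributed Lag Non-Linear Analysis of Temperature-Mortality
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-city time-series studies of the association
    between daily mean temperature and mortality. Implements cross-basis
    construction for distributed lag non-linear models (DLNM), first-stage
    (quasi-)Poisson regression per city with spline adjustment for
    confounders and seasonality, second-stage multivariate random-effects
    meta-analysis with REML estimation and best linear unbiased prediction
    (BLUP), minimum-mortality-temperature estimation, and decomposition of
    the attributable mortality burden into cold/heat and extreme/moderate
    components with Monte Carlo empirical confidence intervals. Includes a
    synthetic multi-city data generator with a known exposure-lag-response
    surface so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
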