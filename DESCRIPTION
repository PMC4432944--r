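Package: heatlag
Title: Distributed Lag Non-Linear Models for Temperature-Mortality
    Case-Crossover Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the non-linear and delayed (lagged)
    association between daily ambient temperature and cause-specific
    mortality counts. Implements the distributed lag non-linear model
    (DLNM) cross-basis -- a quadratic B-spline basis over temperature
    crossed with a natural cubic spline basis over lag -- embedded in a
    time-stratified case-crossover design fitted by overdispersed
    (quasi-)Poisson regression, with QAIC/QBIC model selection,
    relative-risk surfaces with Wald confidence intervals,
    population-weighted aggregation of multi-station temperature records,
    sensitivity analyses over maximum lag and stratum window length, and a
    synthetic-data generator with known ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
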