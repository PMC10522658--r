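Package: ccdlnm
Title: Time-Stratified Case-Crossover Analysis with Distributed Lag
    Non-Linear Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating short-term associations between daily
    ambient temperature and acute health events using a time-stratified
    case-crossover design coupled with distributed lag non-linear models
    (DLNM). Includes population-weighted aggregation of gridded weather to
    ZIP-level exposure series (with relative humidity derived from
    temperature, specific humidity and pressure), cohort construction from
    diagnosis-coded admission records, construction of matched strata with
    lagged exposures, natural-spline cross-bases, a Newton-Raphson
    conditional logistic likelihood fitter with AIC-based selection of
    spline degrees of freedom, delta-method confidence intervals for
    cumulative percent changes in visit rates, and a synthetic-data
    generator with a known exposure-lag-response surface for
    parameter-recovery and coverage testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    yaml
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
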