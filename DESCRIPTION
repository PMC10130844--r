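Package: ccdlnm
Title: Case-Crossover Distributed Lag Non-Linear Models for Heat and
    Acute Health Encounters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-stratified case-crossover analyses of daily
    ambient temperature and acute healthcare encounters, built around a
    distributed lag non-linear model (natural cubic spline in exposure,
    unconstrained integer lags) estimated by conditional logistic
    regression on matched day strata.  Includes citywide exposure-series
    construction from weather-station records, ICD-9 based cohort and
    outcome classification for mental-health encounter studies,
    minimum-risk-temperature referenced cumulative odds ratios with Wald
    intervals, Cochran's Q subgroup heterogeneity, sensitivity analyses
    (humidity adjustment, month restriction), and a synthetic-data
    generator that emulates the warm-season study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    splines,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
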