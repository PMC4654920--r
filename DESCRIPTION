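Package: coldcalls
Title: Weather-Driven Modelling of Daily Emergency-Call Counts with
    Negative Binomial GLARMA Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling daily counts of health-related emergency
    calls as a function of weather. Implements the full workflow from a raw
    daily series (calls, active subscribers, minimum/maximum temperature,
    relative humidity) to a fitted count time-series model: 7-day trailing
    covariate averages, orthogonal-polynomial design matrices with weekday
    and month dummies and a subscriber offset, AIC-based polynomial degree
    selection and term pruning, Poisson and negative binomial generalized
    linear autoregressive moving-average (GLARMA) estimation at sparse
    autoregressive lags, overdispersion and probability integral transform
    diagnostics, nonlinear temperature effect curves with delta-method
    confidence bands, and detection of a critical cold-temperature
    threshold. A synthetic-study generator with known ground truth makes
    every stage testable without access to proprietary call data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
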