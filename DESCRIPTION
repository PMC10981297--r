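Package: esmnet
Title: Temporal Symptom Networks from Experience-Sampling Data
Version: 0.1.0
Authors@R:
    person("esmnet", "developers", email = "esmnet@example.org", role = c("aut", "cre"))
Description: Estimates temporal (lag-1 directed) and contemporaneous
    (partial-correlation) symptom networks from daily experience-sampling
    data using node-wise multilevel vector autoregression with orthogonal
    random effects. Includes a synthetic daily-diary generator with known
    person-specific VAR(1) dynamics, missing-data handling by listwise
    deletion or moving-average imputation, KPSS stationarity checking,
    daily Cronbach's alpha, significance-masked network construction with
    feedback-loop enumeration, and raw-score strength centralities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
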