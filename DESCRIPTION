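Package: treatcascade
Title: Sequential Treatment Cascade Models for Depression Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the sequential delivery of depression treatments to a
    cohort as an absorbing Markov chain: patients who do not respond to one
    treatment step are offered the next, until a target fraction of the
    cohort has responded. Provides per-step response-rate schedules
    (constant, geometrically or linearly declining), conversion of
    standardised-mean-difference effect sizes to response rates via the
    log-odds transform, a deterministic cohort cascade with configurable
    rounding, the fundamental-matrix analytic cross-check, a patient-level
    Monte Carlo simulator with schedule recovery, and scenario suites for
    benchmarking how much a treatment innovation reduces the excess
    treatments a cohort needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
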