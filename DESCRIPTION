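Package: scanprofiler
Title: Scoring, Normative Distribution Fitting and Individual Profiling
    for Computerized Social-Cognition Test Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sessions of a computerized social-cognition
    test battery (theory of mind, irony, metaphor, emotional prosody, social
    perception). Scores per-domain response rates and response times, fits
    normative models (normal, Poisson, exponential, power-law) to a control
    cohort's binned response-rate distributions by sum-of-squared-residuals
    model selection on the cumulative scale, refits low-end tails, compares
    cohorts with normality-gated two-group tests and threshold-trimmed
    matched subgroups, and profiles individual respondents against the norms
    with a two-dimensional rate-by-time quadrant classification and
    per-domain placements. Includes a seedable synthetic-cohort generator so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
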