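Package: lekrem
Title: Relational Event Models for Lekking Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuous-time relational event models (REM) for timestamped
    behavioural event streams on a lek: a constrained piecewise-constant
    hazard model with history-dependent predictor statistics, posterior-mode
    estimation with Gaussian priors, BIC model selection between alternative
    fixed-effect schemes, a forward Gillespie-style simulator driven by an
    exogenous event scaffold, in-silico treatment experiments, and a
    synthetic-data generator for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
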