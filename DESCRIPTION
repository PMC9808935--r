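Package: valvecea
Title: Cost-Effectiveness Modelling of Transcatheter Versus Surgical
    Aortic Valve Replacement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-effectiveness model comparing
    transcatheter aortic valve implantation (TAVI) with surgical aortic
    valve replacement (SAVR) in high-risk aortic-stenosis patients from a
    healthcare-payer perspective. Implements a 30-day decision-tree stage
    feeding a nine-state lifetime Markov cohort model (NYHA classes I-IV,
    their post-stroke counterparts, and death), incremental
    cost-effectiveness arithmetic with dominance handling, net monetary
    benefit, probabilistic sensitivity analysis with Beta/Gamma moment
    matching, cost-effectiveness acceptability curves, one-way (tornado)
    sensitivity analysis, and a patient-level microsimulation used as an
    independent validation oracle for the cohort engine. Model parameters
    are supplied through a validated YAML configuration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
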