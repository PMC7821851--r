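Package: escrisk
Title: Individualized 5-Year Absolute Risk Estimation for Esophageal
    Squamous Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to build and evaluate Gail-type absolute risk models for
    esophageal squamous cell carcinoma (ESCC) from frequency-matched
    case-control data. Includes a synthetic-cohort generator with a
    multiplicative odds structure and registry-style age- and sex-specific
    rate tables; crude and multivariable odds-ratio estimation by
    Newton-Raphson logistic regression with two-phase forward selection,
    re-screening and interaction screening; Bruzzi-type population
    attributable risk; competing-mortality-adjusted 5-year absolute risk
    projection with risk grids and number-needed-to-investigate; and
    ROC/AUC evaluation with 10-fold and leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
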