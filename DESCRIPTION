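Package: frailtyaudit
Title: Construction, Bias Decomposition and Auditing of Frailty Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct deficit-accumulation frailty indices
    (Functional Domains, Burden, and Biologic Syndrome models) from
    cohort data, decompose each index into the information carried by its
    theory-based input variables plus the residual "bias" introduced by
    data manipulation (ordinal rescaling, right-censored sums,
    stratified-quantile categorization, dichotomization), interpret
    indices and statuses with forward-stepwise AIC selection, compare
    mortality prediction across index representations with discrete-time
    (person-period logistic) survival models, and exhaustively enumerate
    equal-weight k-item alternative indices. Includes a synthetic cohort
    generator emulating the statistical structure of an aging panel
    study (age-graded correlated deficits, sex- and body-size-dependent
    performance measures, survey weights, discrete-time mortality
    follow-up) so that the full audit pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
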