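Package: timepref
Title: Measurement and Predictive Evaluation of Time-Preference Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for administering, scoring, and evaluating tests of
    intertemporal choice (delay discounting). Implements three families of
    time-preference tests -- fixed-item forced choice, an adaptive
    probabilistic-bisection test that estimates the one-month discount
    factor, and a free-response matching test -- together with simulated
    respondents, criterion-variable coding and exclusion rules, and an
    evaluation engine that contrasts in-sample association (R-squared,
    Efron's R-squared) with cross-validated predictive accuracy against
    baseline statistics. Also provides the large-sample patience-pair
    analysis: a nine-term log probit/quantile model, a maximally flexible
    nominal class-based model used to demonstrate overfitting,
    nonparametric association tests with Holm-Bonferroni correction, and
    reliability-as-self-prediction reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    quantreg,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
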