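Package: implicate
Title: Statistical Implication Analysis for Binary Outcomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Asymmetric implication analysis for dichotomous variables.
    Implements a full-information implication index on smoothed fourfold
    (2x2) tables that combines direct evidence (how strongly the target
    outcome is enriched given the source) with contrapositive evidence
    (how strongly absence of the source is enriched given absence of the
    target), together with a classical counterexample-rarity intensity,
    bootstrap confidence intervals and significance for every ordered
    pair of outcomes, stratified re-analysis, directed implication-graph
    construction with DOT/JSON export, and a synthetic binary-cohort
    generator with planted implicative structure for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
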