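Package: wqlame
Title: Lameness Scoring, Expert Acceptability and Compensation in
    Welfare Quality Style Aggregation
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study whether hierarchical aggregation of herd-level
    animal-welfare measures masks lameness problems that experts consider
    unacceptable.  Implements herd lameness scoring for dairy cattle
    (weighted prevalence index, non-linear welfare-score transform,
    category bands and a configurable aggregation skeleton up to an
    overall farm category), cumulative-link mixed models for ordinal
    expert acceptability ratings (logit link, equidistant thresholds,
    respondent random intercept, Gauss-Hermite quadrature, AIC model
    selection), panel cleaning rules for nonsensical respondents, and a
    compensation comparison stage that cross-tabulates farm categories by
    lameness profile and contrasts them with predicted expert
    acceptability.  Seeded synthetic-data generators emulate the herd and
    expert-panel designs so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
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
    numDeriv,
    withr,
    yaml
Config/testthat/edition: 3
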