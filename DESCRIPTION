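Package: faersddi
Title: Drug-Drug Interaction Signal Detection from Spontaneous Adverse
    Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for detecting drug-drug interaction (DDI) signals
    in spontaneous adverse event reporting data of the FAERS kind: parsing
    and deduplicating quarterly ASCII report tables, normalizing verbatim
    drug names to ingredients, building an indication-defined cohort with
    MedDRA term rollup, fitting Firth-penalized logistic interaction
    models per (drug, co-medication, adverse event) triple, measuring
    interaction on the additive scale (relative excess risk due to
    interaction with delta-method confidence intervals) and on the
    multiplicative scale, stratified age and gender disparity odds
    ratios, concordance against a graded reference interaction table, and
    a Monte Carlo empirical p-value for the overlap. A synthetic report
    generator built on the same logistic model makes every stage testable
    at desk scale without access to the full reporting database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
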