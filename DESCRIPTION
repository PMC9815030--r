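Package: spaudit
Title: Standardized-Patient Audit Analysis of Diabetes Care Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing standardized-patient (SP) audit studies of
    type 2 diabetes care in tiered health systems. Scores SP-provider
    interaction records against a clinical guideline checklist (recommended
    questions and examinations, correct diagnosis, correct treatment), builds
    tier-stratified comparison tables with between-tier significance tests,
    fits linear and logistic correlate models with average marginal effects,
    and evaluates a three-tier referral care-cascade model that yields the
    system-level probability that a patient is correctly treated, with
    parametric-bootstrap uncertainty and sensitivity analysis. Includes a
    deterministic 126-provider worked-example fixture and a seeded synthetic
    cohort generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
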