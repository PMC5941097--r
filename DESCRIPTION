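Package: cohortforge
Title: Cohort Identification and Surveillance Reporting for Longitudinal Patient-Level Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, scriptable engine for electronic-health-record
    phenotyping on longitudinal patient-level tables. Reusable clinical-order
    templates (ICD-9 exact/prefix/range code sets, drug-name sets) drive
    declarative cohort identifications with first-occurrence index events,
    index-relative inclusion/exclusion windows, and full attrition provenance.
    Identified patient lists form a hierarchical data mart that later
    identifications can chain from; a report service summarises any list as a
    characteristics table, a longitudinal incidence or treatment-proportion
    trend, or a root-to-leaf attrition report. A synthetic-data module
    generates claims-like datasets in a deterministic fixture mode (exact
    attrition counts by construction) and a stochastic population mode, and
    ships a complete new-user study of the anti-osteoporosis treatment gap
    after hip or vertebral fracture as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
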