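Package: burnoutscreen
Title: Burnout and Psychological Distress Screening Engine (GHQ-12, CBI, SUS)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring engine for two free mental-health screening instruments
    and their combination into a rule-based burnout self-assessment. Implements
    bimodal scoring of the 12-item General Health Questionnaire (GHQ-12) with a
    configurable distress threshold, subscale scoring of the 19-item Copenhagen
    Burnout Inventory (CBI) with low/moderate/high level classification and an
    overall risk combination rule, a four-outcome diagnosis (critical, moderate,
    great, contradictory), longitudinal history tracking with per-dimension
    trend reports and retest scheduling, and System Usability Scale (SUS)
    scoring from per-respondent answers or aggregated count tables. A seeded
    respondent simulator with controllable distress and burnout severity makes
    every pipeline stage testable without collecting data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
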