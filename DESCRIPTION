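Package: hboctriage
Title: Hereditary Breast and Ovarian Cancer Screening Triage Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable triage engine for regional hereditary breast and
    ovarian cancer (HBOC) screening programs organised on a Spoke/Hub model.
    Scores family histories with a questionnaire grid, evaluates direct
    referral criteria for genetic counseling, classifies lifetime-risk
    profiles behind a pluggable risk-model contract, generates per-woman
    surveillance schedules, and accounts for the multistep screening funnel
    with one-decimal percentage reporting. Includes a synthetic pedigree
    generator with autosomal-dominant carrier transmission and age-dependent
    cancer penetrance so every pipeline stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
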