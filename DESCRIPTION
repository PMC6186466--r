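Package: strokecoi
Title: Prevalence-Based Cost-of-Illness Estimation for Stroke from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for prevalence-based cost-of-illness
    (COI) estimation of stroke from health-insurance claim records. Computes
    direct medical costs (covered inpatient/outpatient treatment, non-covered
    care, medication, CPI-adjusted assistive devices), direct non-medical
    costs (outpatient transportation, inpatient caregivers), and indirect
    costs under the human-capital approach (productivity lost to care
    episodes and to premature death), then assembles breakdown tables with
    percentage shares and per-case costs. Includes a seeded synthetic claims
    generator calibrated to the demographic structure of the 2015 South
    Korean stroke cohort, so the full pipeline is testable without access to
    the national insurance claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
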