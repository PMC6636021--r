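Package: htnworkforce
Title: Needs-Based Health Workforce Estimation for Nurse-Led Hypertension Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A needs-based workforce estimation model for task-shifted
    hypertension management in low-resource primary care. The clinical
    protocol is represented as data (provider types, clinician-frequency
    combinations, per-trip encounter schedules, and 6-month re-assessment
    transition rules); a deterministic expected-value cohort engine projects
    patient occupancy and monthly encounter demand per provider under
    ramp-up (cumulative year-end targets) or steady-state (constant monthly
    enrollment) scenarios with optional attrition; a capacity model converts
    provider contact minutes and minutes-per-encounter into encounters per
    month per full-time equivalent; and the two combine into monthly and
    yearly FTE requirements with sensitivity sweeps. A patient-level
    stochastic microsimulation over the same protocol serves as a
    brute-force validation oracle for the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
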