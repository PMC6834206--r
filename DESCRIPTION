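Package: hfcompanion
Title: Heart Failure Self-Care Triage, Instrument Scoring, and Pilot Trial Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a mobile heart-failure (HF) self-care
    monitoring program: zone-based symptom and weight-gain triage with
    escalating (dry-run) alert actions, NYHA severity indexing and
    medication-reminder scheduling; scoring for a patient-reported outcome
    battery (PHQ-9, AHFKT, MMAS-8, SCHFI subscales, KCCQ, FSSQ, CIRS) and a
    screening eligibility gate; engagement analytics over timestamped
    feature-access logs; breathing-biofeedback and walking feedback scoring
    against a six-minute-walk reference equation; and a pilot two-arm
    change-score analysis with pooled t-tests, partial eta squared effect
    sizes, and sample-size projection. Seeded synthetic-cohort generators
    emulate patient weight trajectories, app-access logs, and blocked
    two-arm outcome tables so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
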