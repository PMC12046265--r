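Package: hearttriage
Title: Rule-Based Cardiac Symptom Triage, Wellness Content Selection, and
    Usability Statistics
Version: 1.0.0
Authors@R:
    person("Holly", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational core of a chatbot-guided self-management tool for
    women living with cardiac pain. Provides the stored Event Profile data
    model, the rule-based Heart Check triage algorithm (red/yellow/green level
    of care from symptom similarity, the high-risk symptom rule and 24-hour /
    7-day onset windows), the 7-domain Wellness Check with threshold-driven
    library content recommendation, a deterministic scripted dialogue engine
    with a check-in scheduler, System Usability Scale scoring with pooled
    summary statistics and two-group confidence intervals, and a seeded
    synthetic-cohort generator so every component is testable without any
    real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
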