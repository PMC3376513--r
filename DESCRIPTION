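Package: steptailor
Title: Pedometer-Based, Computer-Tailored Step Advice and Trial Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pedometer-based, computer-tailored physical activity
    feedback built around the 10,000 steps/day goal: processing of 7-day
    step logs (non-ambulatory activity conversion, truncation, validity
    rules), transtheoretical-model stage-of-change classification, a
    rule-driven message library with goal schedules and progress feedback,
    the two-arm trial statistics used to evaluate such interventions
    (Welch t, Pearson chi-square, two-timepoint mixed repeated-measures
    ANOVA, intent-to-treat imputation), and a seeded synthetic-cohort
    generator so the full pipeline can be exercised without participant
    data. Includes a command-line interface.
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
    withr
Config/testthat/edition: 3
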