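Package: gslond
Title: Online False Discovery Rate Control for Group-Sequential Platform Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online control of the false discovery rate (FDR) for platform
    trials in which treatment arms enter over time and share a common control
    arm. Implements the LOND procedure (significance Levels based On Number of
    Discoveries) and its group-sequential extensions gsLOND, gsLOND.II,
    gsLOND.III and their combination, which admit one interim analysis per arm
    with early stopping for efficacy or futility. Provides O'Brien-Fleming and
    Pocock type alpha-spending evaluation, exact two-stage group-sequential
    boundary computation on the one-sided p-value scale (including the
    increment-exhausting recalculation used by gsLOND.II), an event-driven
    decision scheduler for overlapping hypotheses, budget allocation sequences
    for the hypothesis stream, a Monte-Carlo platform-trial simulator with
    concurrent or pooled (non-concurrent plus concurrent) controls and
    fixed-budget arm replacement, and the operating-characteristic metrics
    (empirical FDR, average power, saved sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
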