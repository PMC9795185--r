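Package: ccakit
Title: Scoring, Normative Cut Points, and Test-Retest Reliability for the
    Concussion Challenge Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development pipeline for the Concussion Challenge Assessment
    (CCA), a six-task gross motor assessment for paediatric concussion.
    Provides a seeded synthetic-cohort generator emulating normative
    youth-athlete samples and paired test-retest designs; the error-modified
    0-4 scoring engine for the six tasks; derivation of normative cut points
    by the mean +/- SD and quartile methods with error-free filtering and
    age/sex stratification; item-difficulty and ceiling-effect diagnostics;
    and single-measure intraclass correlation test-retest reliability with
    confidence intervals, stability classification, and the outcome versus
    exertion item partition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
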