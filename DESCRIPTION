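Package: calfort
Title: Simulating Calcium Fortification of Flour from Dietary Recall Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates usual (habitual) calcium intake distributions from
    24-hour dietary recall data by life-stage group, simulates fortification
    of flour with calcium at a configurable level (default 156 mg calcium per
    100 g flour), and quantifies effectiveness (prevalence of intakes below
    the Estimated Average Requirement) and safety (prevalence above the
    Tolerable Upper Intake Level) before and after fortification, including
    the target-prevalence and initial-gap calculations used in fortification
    planning. Ships a seeded synthetic-survey generator with closed-form
    ground truth so every pipeline stage is testable without access to
    national survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
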