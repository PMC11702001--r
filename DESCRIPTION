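Package: suddenstep
Title: Detection and Analysis of Sudden Gains in Weekly Outcome Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying sudden gains - large between-week symptom
    improvements - in weekly patient-reported outcome trajectories such as
    those collected during internet-delivered cognitive therapy for social
    anxiety disorder. Implements the three-criterion sudden-gain
    classification (absolute cutoff, relative drop, and a pooled-standard-
    deviation stability test with missing-data-adjusted Student-t critical
    values), reversal tracking, primary-gain selection, and cohort-level
    summaries. Provides linear mixed-effects analyses of outcome differences
    between gainers and non-gainers and of process-measure changes across
    consecutive timepoints around the gain, with Bonferroni correction and
    Cohen's d effect sizes. Includes a calibrated synthetic-cohort generator
    with oracle-certified injected gains so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    nlme,
    emmeans,
    jsonlite,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
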