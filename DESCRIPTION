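Package: prosodpass
Title: Double-Pass Reverse Correlation for Speech Prosody Perception
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for representation + noise psychophysics of speech
    prosody. Generates double-pass reverse-correlation experiments on
    pitch contours (per-segment Gaussian pitch perturbations in cents),
    simulates two-stage template-matching observers with additive
    Gaussian internal noise, estimates per-participant internal
    representations as RMS-normalised classification images, infers
    internal noise and decision criterion from double-pass response
    consistency and bias by exhaustive-search inversion of a Monte Carlo
    observer model, and provides group-level statistics (rank-sum
    comparisons and bootstrap-CI least-squares regressions) for cohort
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
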