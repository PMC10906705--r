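Package: aerosolwatch
Title: Quantifying Aerosol and Droplet Generation During Clinical Procedures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying excess airborne particle production during
    clinical procedures from six-channel optical particle-counter time series.
    Implements whole-procedure comparisons under a log-normal count model
    (duration-normalised effective counts, median-filter background
    subtraction, Welch t-tests on log counts), event-based excess analysis
    around annotated procedure events (local-baseline subtraction,
    null-reference sampling, log-normal/normal mixture fits, bootstrap
    fold-change inference), cohort comparison statistics, and a synthetic
    two-arm study generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    stats,
    utils,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
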