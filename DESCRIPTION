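Package: avalanchr
Title: Neuronal Avalanche Analysis of Multichannel Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects negative local field potential (nLFP) events in
    multichannel cortical recordings, extracts neuronal avalanches from
    time-binned event rasters, fits the power-law exponent (alpha) of the
    avalanche size distribution on log-log axes, validates fits against
    shuffle surrogates, and compares alpha across experimental groups with
    Student's t-test. Ships a branching-process simulator with an exact
    Borel-distribution oracle so every stage of the pipeline can be
    validated against ground truth without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
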