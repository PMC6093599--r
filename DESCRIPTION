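Package: thetaseq
Title: Theta/Alpha Phase Coding of Serial Order in Working-Memory
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting stimulus-selective cortical
    recording sites and testing whether the theta/alpha phase of broadband
    gamma activity during working-memory maintenance encodes serial list
    position. Provides a synthetic Sternberg-session generator with nested
    oscillations, preprocessing (polyphase resampling, common-average
    reference, DFT line-noise removal, epoching, kurtosis-based artifact
    rejection), sliding-window FFT time-frequency analysis, mutual-information
    letter selectivity with permutation tests, phase-amplitude coupling as
    raw-signal/envelope coherence, a circular template-matching permutation
    test for phase-ordered gamma, and site-level group statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
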