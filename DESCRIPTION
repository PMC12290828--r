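Package: pingdecode
Title: Time-Resolved EEG Decoding and Permutation Inference for
    Visual-Impulse (Ping) Memory Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for cued-recall
    electroencephalography (EEG) experiments that probe memory
    reinstatement with brief visual impulses ("pings"). Provides a
    synthetic-data generator for the full trial design and epoched EEG
    signal (1/f plus oscillatory noise, ping-evoked responses, and
    category-specific patterns with tunable onset-latency
    regularization), Gaussian-windowed and Hilbert band-power feature
    extraction, time-resolved shrinkage-regularized linear discriminant
    decoding with stratified cross-validation and shuffled-label
    permutations, two-level Monte-Carlo permutation statistics with
    Benjamini-Yekutieli false-discovery-rate control, the
    peak-order-distance (POD) test on condition-specific decoding peaks,
    event-related potential contrasts, and a reproducible pipeline
    driver. Results are tidy tibbles with broom-style tidy() and
    glance() methods and ggplot2 autoplot() figures.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
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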