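Package: tseeg
Title: Tsallis Entropy Features for EEG Emotion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for recognising emotional states from multichannel
    electroencephalography (EEG). Trials are band-decomposed into the
    classical EEG rhythms (theta, alpha, beta, gamma and the full band),
    summarised by sliding-window Tsallis entropy features parameterised by
    the nonextensive index q, and classified with a k-nearest-neighbour
    model under repeated stratified holdout. Includes the 62-channel
    extended 10-20 scalp montage with hemisphere and quadrant region
    partitions, per-channel / per-rhythm / per-region performance analysis
    with top-quartile channel selection, and a synthetic EEG generator
    that plants band-limited complexity differences between classes so the
    whole pipeline is testable without access-restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
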