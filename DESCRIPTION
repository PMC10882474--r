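Package: receptr
Title: Receptivity and Momentary Affect Modelling for Wearable EMA Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the relationship between ecological
    momentary assessment (EMA) receptivity and momentary affect from
    wearable physiology. Provides a seeded synthetic cohort generator
    (EMA logs plus RR-interval, electrodermal, skin-temperature and
    accelerometer streams), a windowed physiological feature battery
    (time- and frequency-domain heart-rate variability, wavelet and
    statistical electrodermal features, temperature and movement
    summaries), sliding-window segmentation with pseudo-labelling of
    receptivity and affect, personalised receptivity classifiers and
    heteroscedastic affect regression with per-prediction uncertainty,
    cluster-based profiling of receptive versus non-receptive states,
    and estimation of the affect-sampling bias a receptivity-triggered
    EMA policy would introduce.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
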