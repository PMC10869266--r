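Package: riborunoff
Title: Polysome Profile Quantification and Ribosome Runoff Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying polysome profiles (baseline correction,
    peak detection, monosome/polysome segmentation with a fixed
    monosome-to-polysome offset, trapezoidal area integration and
    polysome-to-monosome ratios), for fitting exponential runoff-decay
    kinetics to harringtonine time courses (rate constant and inactive-ribosome
    plateau), for mechanistically simulating ribosome runoff over an mRNA
    population with an inactive-granule fraction and in-silico EDTA, puromycin,
    RNase1 and NMDA treatments, and for a fraction-resolved proteomics
    differential-abundance analysis (variance-stabilizing calibration, mixed
    MNAR/MAR imputation, moderated testing and polysome/monosome shift
    classification).
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
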