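Package: numerp
Title: Synthetic ERP Experiments and Topographic Microstate Analysis for Visual Numerosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing event-related potential (ERP)
    experiments on visual shape and numerosity perception. Generates Gaussian-blob
    stimulus layouts (elements on polygon vertices, on contours, or inside virtual
    shapes), balanced randomized trial schedules, and ground-truth-known synthetic
    64-channel EEG recordings with condition-dependent evoked components (N1, N2,
    and a left mid-frontal numerosity effect), ocular artifacts and behavioural
    data. Implements the matching analysis chain: zero-phase band-pass filtering,
    regression-based blink correction, epoching with amplitude-threshold artifact
    rejection, per-condition averaging, component mean-amplitude statistics with
    repeated-measures ANOVA and Greenhouse-Geisser correction, reference-free
    topographic measures (global field power, global map dissimilarity), the
    randomization TANOVA with a minimum-duration criterion, and atomize-and-
    agglomerate hierarchical clustering (AAHC) microstate segmentation with a
    cross-validation criterion and global-explained-variance back-fitting.
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
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
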