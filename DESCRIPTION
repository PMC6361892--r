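Package: alphaconn
Title: Alpha-Band EEG Functional Connectivity with dbWPLI and Network-Based Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for sensor-space EEG functional
    connectivity analysis in infant cohort studies. Continuous multichannel
    recordings are segmented around validity annotations, cut into
    overlapping one-second epochs, Hanning-tapered and Fourier transformed,
    and summarised as debiased weighted phase lag index (dbWPLI)
    connectivity matrices in a narrow alpha band. Group differences over
    the connectivity network are tested with the Mann-Whitney variant of
    Network-Based Statistics (maximum supra-threshold component extent
    against a permutation null), and scalar connectivity summaries feed
    univariate group comparisons (assumption-driven t-test or Mann-Whitney
    dispatch, exact or asymptotic p-values, z-based effect sizes) and
    brain-behaviour Spearman correlations with winsorizing and
    Benjamini-Hochberg false discovery rate control. A synthetic EEG and
    cohort generator with planted narrow-band phase-lagged coupling,
    zero-lag mixing and 1/f background noise provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
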