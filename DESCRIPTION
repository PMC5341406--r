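Package: bimodyn
Title: Single-Cell Protein Dynamics: Bimodality Screening and Cell-Fate
    Analysis for Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-cell dynamic-proteomics experiments in
    which endogenously tagged proteins are followed by two-channel time-lapse
    fluorescence microscopy after drug treatment. Provides a synthetic-data
    generator (per-cell trajectory panels and rendered two-channel movies with
    ground truth), an image-analysis chain (flat-field/background correction,
    Otsu-plus-watershed segmentation of nuclei and cytoplasm, reverse-time
    nearest-centroid tracking, morphology-based mitosis and death detection,
    per-cell quantification and nuclear/cytoplasmic ratios), per-cell interval
    slope statistics over a late analysis window, a three-test
    (t/Kolmogorov-Smirnov/Mann-Whitney) consensus with Benjamini-Hochberg
    correction to call clones with bimodal dynamics, and downstream analyses
    correlating dynamics with cell fate, mitosis timing with death, mean
    dynamic profiles, and clustered dynamics heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
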