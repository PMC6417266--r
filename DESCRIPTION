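Package: enhancerscope
Title: Super-Enhancer Calling and Histone-Mark Quantification from ChIP-Seq Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for enhancer epigenomics: identifies
    distal H3K27ac peaks, stitches them into enhancer regions, ranks them by
    normalized signal and separates super-enhancers from typical enhancers at
    the slope-1 tangent of the scaled ranked-signal curve (the ROSE procedure),
    including a variant in which regions are built from distal H3K4me3 peaks
    but ranked by their H3K27ac signal. Also quantifies mark signal over
    arbitrary regions with per-million normalization, bins the genome for
    inter-mark correlation, links enhancers to adjacent genes and classifies
    their expression change between conditions, and computes histone-peptidoform
    relative abundances with single-mark aggregation and homoscedastic t-tests.
    A bundled synthetic-data generator plants ground truth for every stage so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
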