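Package: comphet
Title: Single-Cell Competence Heterogeneity Analysis for Bacterial Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies heterogeneous competence induction in bacterial
    populations from fluorescence microscopy, flow cytometry and
    population-level kinetics. Implements a single-cell image
    quantification pipeline (percentile contrast stretch, classical
    watershed segmentation with an adapter seam for external segmenters,
    smallest-fraction area filtering, central circular region-of-interest
    selection, raw mean-intensity extraction and per-image min-max
    normalization), reference-anchored percentile-exceedance shift
    statistics for single-cell fluorescence distributions,
    detection-limit-censored transformation-frequency analysis with
    maximum induction-rate estimation, four-parameter logistic fits of
    reporter kinetics, and a seeded synthetic-data generator that
    emulates the measurement structure of competence time-course
    experiments so the whole pipeline is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
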