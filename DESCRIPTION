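Package: blebquant
Title: Quantification of Bleb-Based Amoeboid Motility in Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the amoeboid (blebbing) phenotype of
    confined cells from time-lapse microscopy: intensity-based cell
    segmentation and greedy centroid tracking with quality-control filters,
    moment-based cell morphometrics, a blebbing-activity statistic defined
    as the normalized frame-to-frame shape-difference area, classification
    of expanding versus retracting protrusions, confinement escape-assay
    geometry (boundary distances, escape times, escape angles, elongation
    dynamics, speed and directional persistence), fluorescence linescans
    and cortical/cytoplasmic enrichment ratios, and nested-replicate
    (SuperPlot) statistics with Dunnett and Mann-Whitney tests. Includes a
    synthetic movie generator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    mvtnorm,
    withr
Config/testthat/edition: 3
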