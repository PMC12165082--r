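Package: etcscreen
Title: Exfoliated Tumor Cell Screening from Cytology Slides and Single-Cell Copy Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-arm pipeline for detecting exfoliated tumor cells (ETCs) in
    body-fluid cytology. The genomic arm converts per-cell low-pass
    whole-genome-sequencing bin counts into GC-normalized copy-number ratio
    tracks, applies MAPD quality control, segments profiles with a native
    circular-binary-segmentation implementation, computes autosomal CNA burden,
    and labels cells malignant by clonal concordance. The imaging arm tiles
    whole-slide cytology images, detects cell candidates, filters non-single-cell
    objects with a seven-class quality-control model, segments cells to a uniform
    background, routes them by size, and scores malignancy with two
    specificity-calibrated channel classifiers. A diagnosis layer aggregates
    per-cell calls into slide-level ETC fractions, applies an operating cutoff,
    and reports cohort-level contingency metrics with confidence intervals.
    A synthetic-data module generates clonal single-cell CNA profiles and
    rendered Pap-like slide images with ground truth so the full cascade is
    trainable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    png,
    EBImage,
    nnet,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
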