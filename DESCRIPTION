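Package: histoprox
Title: Random-Forest Proximity Search for Histopathology Photomicrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based similarity search for histopathology photomicrographs
    built on the decision paths of a random forest. Images are standardized,
    described by a fixed 2412-dimensional bank of hand-engineered features
    (color histograms, local binary pattern pyramids, edge-orientation
    histograms, gray-level co-occurrence statistics, moment invariants), by a
    21-patch sum-pooled encoder set representation, by a bag of SIFT clusters,
    and by clinical covariates (tissue type with missingness, marker mention)
    parsed from case text by editable keyword rules. A 1000-tree forest trained
    to classify disease state (nontumor, low grade, malignant) is repurposed for
    search: two cases are as similar as the number of trees that route them
    through identical decision sequences to the same leaf. Includes three-level
    sanity checking (ensemble uncertainty, prediction-vs-expectation, 5x5
    prediction heatmaps), permutation feature importance, ten-fold and
    leave-one-pathologist-out evaluation with weighted AUROC and precision@k,
    permutation-null calibration, rank-sum replicate comparison, and a
    synthetic-corpus generator for fully reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
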