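Package: bearid
Title: Individual Polar Bear Photo-Identification from Whisker-Spot
    Patterns and Observer Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate photographic identification of individual
    polar bears. Implements the automated whisker-spot matcher (three-point
    affine registration to a standard pixel grid, adaptive binarization,
    small-component noise filtering, symmetric Chamfer dissimilarity),
    modified ROC threshold optimization with bootstrap confidence bands,
    confusion-rate statistics (false positive rate, false negative rate and
    their Euclidean error rate) for observer rating matrices, a permutation
    null for pairwise set comparisons, and binomial mixed-model analyses of
    rating repeatability and observer experience. A synthetic-data module
    generates whisker-spot patterns, rendered muzzle photographs at
    controlled quality, trial designs and simulated observers so every
    analysis is exercisable without field photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    png,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmmTMB,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
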