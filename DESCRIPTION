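Package: gmanifold
Title: Consensus Analysis of General-Intelligence Correlates in Cortical Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives many parallel estimates of the general-intelligence
    factor (g) from all one-test-per-domain combinations of a multi-domain
    cognitive battery, associates each estimate with region-of-interest
    (ROI) cortical morphometry (cortical thickness, local gyrification
    index) through covariate-adjusted linear models with permutation-based
    family-wise error control, retains ROIs that are significant in a
    majority of the parallel analyses, and builds stepwise linear models
    that estimate g from the surviving ROIs with K-fold cross-validation.
    Includes a synthetic-cohort generator with known latent structure so
    every stage of the pipeline can be verified against ground truth.
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
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
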