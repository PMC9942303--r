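Package: covtsp
Title: Covariate-Adjusted Top-Scoring Pair Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based top-scoring pair (TSP) and K-TSP classification for
    two-class omics data, with a covariate-adjustment step that regresses each
    feature on clinical covariates and selects pairs from the residuals. Includes
    the pair discriminant score and secondary rank score, greedy selection of
    disjoint pairs with a variance-normalized criterion for choosing the number
    of pairs, repeated stratified cross-validation with six accuracy measures,
    simulation generators for covariate-driven and outcome-driven feature pairs,
    tidy accessors, and ggplot2 visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
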