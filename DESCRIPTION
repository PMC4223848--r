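Package: clqkappa
Title: Inter-Rater Reliability of Categorical Ratings at Point Locations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses inter-rater reliability and spatial association of
    categorical environmental ratings observed at planar point locations,
    such as survey answers about the perceived neighborhood environment.
    Builds first-order nearest-neighbor matched sets within a maximum
    radius (with tie weighting), converts them into weighted
    index-by-neighbor contingency tables, and computes category-specific
    and cross-category kappa statistics together with a colocation
    quotient (CLQ) modified for sampling with replacement.  A
    normalization identity maps CLQ onto the kappa scale via its
    theoretical maximum.  Includes approximate null standard errors, a
    permutation null for validation, a three-criterion procedure for
    deciding whether rating categories can be collapsed without loss of
    reliability, a synthetic-data generator with a latent spatial
    environment, and report rendering in the style of published
    agreement tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
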