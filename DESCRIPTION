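Package: eyescale
Title: Phylogenetic Allometry of Eye Size and Ecological Eye Investment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic comparative analyses of eye-body
    allometry. Provides tree preparation (pruning, tip substitution,
    polytomy grafting and random resolution), phylogenetic generalized
    least squares with maximum-likelihood estimation of Pagel's lambda,
    ordinary least-squares and standardized major axis allometric fits
    with isometry tests and a robust Huber-M variant, exponentiated
    phylogenetic residuals as eye-investment factors, Kruskal-Wallis and
    phylogenetic ANCOVA tests of ecological correlates, an iterative
    Studentized-residual outlier sensitivity procedure, cross-clade
    scaling comparisons, and a seeded synthetic-data generator (Yule
    trees, Brownian traits, habitat states, specimen-level measurement
    noise) so that every pipeline stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
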