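Package: stoichcor
Title: Stoichiometric Correlation Analysis of Metabolite Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects couplings of biochemical reaction rates from metabolomics
    profiles by maximizing the Pearson correlation between positive
    integer-weighted linear combinations of log-transformed metabolite levels
    (stoichiometric correlation, a constrained form of maximal correlation).
    Includes enumeration of pair, triplet and quadruple metabolite splits with
    small-integer stoichiometric weights, analytic and permutation significance
    with Benjamini-Hochberg correction, per-metabolite coupling degrees and
    cross-dataset overlap comparison, mass-action and Michaelis-Menten kinetic
    simulation of reaction networks (with enzyme-complex expansion) to generate
    validation ensembles, and a planted-coupling synthetic benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
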