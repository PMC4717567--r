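Package: hostrangr
Title: Comparative Analysis of Parasitoid Host Range, Ovipositor Morphology
    and Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for testing whether host range and ovipositor
    morphology of parasitoid wasps are constrained by phylogenetic history.
    Builds phylogenetic (patristic), morphological (relative difference of
    species medians) and ecological (binary Bray-Curtis host-range) distance
    matrices; runs simple and partial Mantel permutation tests between them;
    measures phylogenetic signal in binary traits with the D statistic
    against phylogenetically random and Brownian-threshold nulls; and
    compares partitioning schemes of Bayesian phylogenetic analyses with
    penalized harmonic-mean Bayes factors. A synthetic-data module generates
    trees, morphometric measurements and host-record tables with the
    statistical structure the analysis assumes, so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
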