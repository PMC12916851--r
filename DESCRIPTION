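Package: mosqnet
Title: Mosquito Microbiome Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genus-level microbiome network
    analysis of host-associated bacterial communities: prevalence-based
    contaminant identification against negative controls, rarefaction and
    alpha/beta diversity statistics, compositionally robust correlation
    inference (SparCC) implemented from scratch, thresholded signed
    co-occurrence networks with full topology summaries, cross-network
    comparison via Jaccard indices of most-central node sets with exact
    hypergeometric null p-values, attack-based robustness and node-addition
    simulations, and in-silico taxon knockout experiments. Includes a
    synthetic-data generator that plants a known log-scale interaction
    structure so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
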