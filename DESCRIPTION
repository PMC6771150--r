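Package: arowana
Title: Simulation-Based Demographic Inference for Two-Basin SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coalescent simulation, image encoding and convolutional-network
    inference for demographic model selection between two river basins, built
    around the silver arowana (Osteoglossum bicirrhosum) study system. Provides
    a Hudson-style coalescent simulator for four two-deme demographic scenarios
    (panmixia, vicariance and two directed founder-effect colonizations) with
    uniform priors on effective size, divergence time, generation time and
    founder/growth ratios; an encoder that turns sorted haplotype or genotype
    matrices into fixed-shape image tensors; a small convolutional network
    (implemented in compiled code) for 4-way scenario classification and
    multi-output parameter regression scored by RMSE and Spearman's rho;
    SNP diversity and differentiation statistics (observed and unbiased expected
    heterozygosity, inbreeding coefficient, Weir-Cockerham pairwise FST, PCoA on
    identity-by-state distances); and a hierarchical Balding-Nichols generator
    of empirical-like genotype datasets with missing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    vcfR,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
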