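Package: colonystruct
Title: Colony-Structured Population Genetics for Social Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatially sampled social-insect population genetics
    built around colony-structured microsatellite genotypes: GENEPOP import
    and export, colony breeding-system classification (simple, extended,
    mixed families) by Mendelian parental-pair screening and combined-locus
    G-tests, Weir-Cockerham F-statistics, hierarchical AMOVA, exact and
    Monte Carlo tests of heterozygote deficiency, genotypic linkage
    disequilibrium scans, isolation-by-distance analysis (Edwards' chord
    distance, Mantel tests, kernel density of the distance scatter),
    spatial principal component analysis with Moran's I and permutation
    tests, admixture-model Bayesian clustering with Evanno Delta-K model
    selection, and a seeded colony-pedigree simulator (outbred pairs,
    inbred neotenic lines, mixed founder groups) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    ade4,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
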