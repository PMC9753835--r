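Package: popgenmon
Title: Temporal Population-Genetic Monitoring of Microsatellite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for long-term genetic monitoring of recovering wildlife
    populations genotyped at microsatellite loci. Implements spatio-temporal
    grouping of georeferenced multilocus genotypes, genetic diversity
    statistics with hypergeometric rarefaction (allelic richness and private
    allelic richness), Weir-Cockerham F-statistics with permutation tests,
    AMOVA, exact Hardy-Weinberg and composite linkage-disequilibrium tests,
    a two-stage procedure separating Wahlund effects from inbreeding, a
    Bayesian admixture (STRUCTURE-type) Gibbs sampler with run alignment and
    Evanno delta-K model choice, private-alleles gene-flow estimation,
    least-cost-distance Mantel correlograms, and a forward Wright-Fisher
    simulator of bottlenecked, re-connecting subpopulations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
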