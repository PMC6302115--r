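Package: ldpopsize
Title: Linkage Disequilibrium Decay and Effective Population Size from SNP
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tidy tools for characterising linkage disequilibrium (LD) and
    effective population size (Ne) in diploid populations genotyped on dense
    SNP arrays. Provides per-population genotype quality control with an
    exact Hardy-Weinberg test, pairwise within-chromosome r2 (dosage
    correlation and EM haplotype estimators), binned LD-decay curves with
    threshold-distance summaries, historical Ne trajectories from binned LD
    via the Sved/Corbin relationship, single-point contemporary Ne by the
    LD method with Waples bias correction under random-mating or monogamy
    models, method-of-moments relatedness, and PCA of standardised
    genotypes. A forward Wright-Fisher simulator with recombination,
    configurable Ne trajectories and population splits generates panels
    with known truth so every stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
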