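Package: founderflow
Title: Invasion Genetics and Founder-Number Estimation from
    Microsatellite and Mitochondrial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for reconstructing the demographic history of recently
    introduced populations from diploid microsatellite genotypes and
    mitochondrial haplotype data: per-population diversity summaries
    (rarefied allelic richness, private allelic richness, observed and
    expected heterozygosity, haplotype and nucleotide diversity),
    source-population assignment via Weir-Cockerham FST with permutation
    tests and neighbor-joining trees on Cavalli-Sforza chord distances,
    a forward Monte Carlo maximum-likelihood estimator of the effective
    number of founders under a founding-bottleneck plus logistic-growth
    Wright-Fisher model, and a haplotype-resampling estimator of the
    number of maternal founder lineages.  A synthetic-data generator
    with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
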