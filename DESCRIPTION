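Package: ddpopgen
Title: Molecular Population Genetics and Social Evolution Statistics for
    Social Amoebae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diversity statistics (Watterson's theta, nucleotide diversity,
    Tajima's D, Hudson's Fst), linkage-disequilibrium decay profiling with
    permutation testing, recombination-rate inference (four-gamete
    Hudson-Kaplan Rm, a moment estimator, and pairwise composite-likelihood
    estimation of the population recombination parameter rho with a
    Monte-Carlo two-locus lookup table), strain clustering and
    isolation-by-distance tests, and kin-discrimination statistics from
    chimeric fruiting-body experiments, for panels of re-sequenced gene
    fragments from haploid strains such as wild Dictyostelium discoideum
    isolates. Includes a coalescent-with-recombination generator that
    emulates a multi-fragment re-sequencing study design so every analysis
    stage can be exercised end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
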