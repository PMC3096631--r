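Package: pileupcall
Title: Bayesian Consensus Base Calling and Cross-Platform Read Quality
    Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates platform-styled short-read sequencing data (FLX-like,
    GA-like and SOLiD-like profiles) from synthetic bacterial genomes with
    planted single-base substitutions and near-identical repeat regions,
    performs ungapped read mapping under a mismatch budget with best-stratum
    and unique-only multi-mapping policies, estimates empirical 4x4 base
    substitution (read probability) matrices from alignments, calls
    single-base substitutions with a multinomial-likelihood Bayesian
    consensus model under a uniform prior, and evaluates detection
    sensitivity against the planted truth as a function of coverage,
    including a power-law saturation fit TP(n) = T (1 - A n^-B).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    minpack.lm,
    Biostrings,
    S4Vectors,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
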