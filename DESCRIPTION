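Package: sigmapop
Title: Population Genetics and Vertical Transmission Analysis of Insect Sigma Viruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the population genetics and transmission of
    vertically transmitted insect viruses from partial-gene Sanger alignments
    and laboratory cross records. Provides ADAR A-to-G hyper-mutation
    detection and masking against a majority-rule consensus, nucleotide
    diversity and Tajima's D with coalescent-simulation and beta-distribution
    null models, Hudson-Boos-Kaplan K_ST permutation tests of population
    differentiation, rejection-ABC inference of exponential population growth,
    doubling times and TMRCA under an informative molecular-clock prior, exact
    Wilcoxon rank-sum analysis of maternal versus paternal transmission
    crosses, and a coalescent simulator (constant size, exponential growth,
    two-deme splits) with finite-sites mutation and an ADAR tract injector for
    fully synthetic end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
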