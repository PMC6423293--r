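Package: mutaccum
Title: Mutation-Accumulation Line Analysis and Population Genomic Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating spontaneous mutation rates from
    mutation-accumulation (MA) experiments in clonally propagated plants
    such as duckweed, and for relating those rates to standing genetic
    diversity. Implements the de novo candidate filtering cascade used in
    short-read MA studies (hard site filters, callable-depth masks,
    variant-cluster and cross-sample sharing filters, allele-support
    checks), per-line and per-treatment mutation rates with exact Poisson
    (Garwood) confidence intervals, false-negative estimation by
    ancestral-heterozygote recall and by spike-in recall, nucleotide
    diversity, synonymous and nonsynonymous site classification, Tajima's
    D, Hudson's Fst, linkage-disequilibrium decay with Sved-equation
    fitting, and effective population size from theta = 4*Ne*mu. A
    synthetic-data generator emulates the MA design (one ancestor,
    replicate single-descendant lines, binomially sampled allele depths)
    and an infinite-sites coalescent so every stage is testable at desk
    scale with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    minpack.lm,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
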