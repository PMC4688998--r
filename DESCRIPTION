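Package: orchardgs
Title: Genomic Selection for Pedigreed Fruit Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end genomic selection toolkit for multi-family pedigreed
    breeding populations of outbred perennial crops. Simulates pedigreed
    full-sib families with gene-dropped SNP genotypes and ordinal liability
    phenotypes; adjusts phenotypes for year and location effects using
    replicated reference genotypes and computes animal-model BLUPs with
    EM-REML variance components; imputes low-density application genotypes to
    high density with a family haplotype hidden Markov model; fits BayesC-pi
    whole-genome regression by Gibbs sampling to predict genomic breeding
    values; builds pedigree (A) and genomic (G) relationship matrices with
    top-N relatedness summaries and LD-decay diagnostics; and evaluates
    prediction accuracy, Fisher-z confidence intervals, and realized selection
    differentials per family and trait.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    readr,
    jsonlite,
    digest,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
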