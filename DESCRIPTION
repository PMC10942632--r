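Package: ercovar
Title: Evolutionary Rate Covariation Analysis on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes branch-specific relative evolutionary rates (RERs) from
    per-gene phylogenies that share a master topology, correlates them between
    genes to obtain Fisher-transformed evolutionary rate covariation (ERC),
    and tests whether gene sets (protein complexes, pathways) and physically
    interacting protein domains carry elevated ERC.  Includes size-matched
    permutation tests for gene sets, ROC-AUC and one-tailed Mann-Whitney
    ranking of domain pairs within complexes, a proportional-rank statistic
    with nested permutation nulls, and a latent-factor synthetic-data
    generator with known correlation structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
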