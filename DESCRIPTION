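Package: zeronet
Title: Zero-Aware Correlation and Association Networks for Microbial
    Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers microbial association networks from zero-inflated
    operational taxonomic unit (OTU) abundance tables. Implements six
    zero-value treatment policies (zeros as-is, k-nearest-neighbour
    imputation, pseudo-value filling, paired-zero exclusion with and
    without unpaired filling, and complete-case analysis), sequential
    pairwise Pearson/Spearman/Kendall correlation with a minimum-overlap
    rule, a from-scratch SparCC estimator for compositional data, and
    signed co-occurrence/co-exclusive network construction with topology
    metrics, hub subnetworks and consensus networks. Includes a
    zero-inflated synthetic profile generator with known latent
    correlation structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    tibble,
    tidyr,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
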