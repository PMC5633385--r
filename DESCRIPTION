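Package: clusterkin
Title: Taxon-Aware Analysis of Clustered Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of protein orthology clusterings (OrthoFinder,
    OrthoMCL and compatible tools) under arbitrary, user-defined groupings of
    the input proteomes. Classifies clusters as singleton, taxon-set-specific
    or shared; detects strict and "fuzzy" single-copy orthologs for
    phylogenomics; draws pan-proteome rarefaction curves; runs pairwise
    protein-count representation tests (Mann-Whitney U, Welch or Student t)
    with volcano summaries; infers Dollo-parsimony synapomorphic clusters on a
    user-supplied tree topology; aggregates InterProScan functional annotation
    into coverage-thresholded representative cluster annotations; and reports
    clusters containing genes of interest. Includes a deterministic synthetic
    data generator producing internally consistent input bundles with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    phangorn,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
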