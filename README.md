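# clusterkin

Taxon-aware downstream analysis of protein orthology clusterings in R.

Orthology inference tools (OrthoFinder, OrthoMCL and kin) reduce the
proteomes of many species to clusters of putatively homologous proteins, but
leave the interesting questions open: which clusters are diagnostic of a
clade or a phenotype, which are single-copy and usable for phylogenomics,
how does the pan-proteome grow as taxa are added, where are gene families
expanded or contracted, and what do the clusters *do*? `clusterkin` answers
these questions for user-defined groupings of the input proteomes — by
systematic taxonomy (NCBI TaxIDs), by competing phylogenetic hypotheses, or
by any phenotype attribute (host, lifestyle, habitat) supplied in a small
config table. It is aimed at comparative genomicists who already have a
clustering and annotation in hand and want transparent, reproducible,
scriptable analysis in the tidyverse idiom: every function takes a data
frame and returns a tibble.

## What it computes

For proteomes grouped into **taxon sets** (the levels of each config
attribute), every cluster is classified as

* `singleton` — one protein,
* `specific` — ≥ 2 proteins, all from one taxon set,
* `shared` — proteins from ≥ 2 taxon sets,

and the package derives:

* **Single-copy orthologs.** Strict SCOs (exactly one protein per proteome)
  and *fuzzy* SCOs: all per-proteome copy counts `c` within
  `[min, max]` and a fraction ≥ `target_fraction` of proteomes at exactly
  `target_count` copies.
* **Rarefaction curves.** Repeated random proteome sampling per set with
  cumulative counting of distinct nonsingleton clusters — the pangenome
  rarefaction framework applied to pan-proteomes.
* **Representation tests.** Per cluster, two-sided Mann–Whitney *U*
  (exact enumeration at small n, normal approximation with tie and
  continuity correction otherwise), Welch or Student tests on per-proteome
  protein counts between two sets (zeros included for absent members), with
  `log2` fold changes of means and volcano plots.
* **Dollo-parsimony synapomorphies.** On a user tree, a cluster is
  synapomorphic for the branch to a node when all member proteomes lie
  under the node and every child subtree is represented; graded into
  complete-presence (100% taxon coverage) and partial-absence
  (≥ `node_taxon_cov`) classes. Apomorphies (proteome-private clusters) are
  listed per proteome.
* **Representative functional annotation.** InterProScan output (Pfam, IPR,
  GO, SignalP namespaces) lifted to cluster level through two coverage
  thresholds, `domain_taxon_cov` and `domain_protein_cov`; plus per-cluster
  length statistics, secreted fraction, and term entropy
  `H = -Σ p_d log2 p_d` with `p_d` the incidence-weighted term frequency.
* **Clustering overviews.** Cluster-size histograms with a reference
  power-law fit `n(s) = C·s^(−γ)`, and a proteome co-occurrence network in
  GraphML.

## Worked example

The package ships a three-proteome worked example (proteomes `A`, `B`, `C`
with 12 proteins in 6 clusters) used throughout the documentation:

```r
library(clusterkin)
toy <- toy3_fixture()

cluster_summary(toy$clustering)
#> # A tibble: 6 × 3
#>   cluster_id  size proteome_count
#>   <chr>      <int>          <int>
#> 1 OG0            3              3
#> 2 OG1            2              2
#> 3 OG2            2              1
#> 4 OG3            1              1
#> 5 OG4            3              3
#> 6 OG5            1              1

find_true_scos(toy$clustering)$cluster_id
#> [1] "OG0" "OG4"

classify_clusters(toy$clustering, toy$config, "host") |>
  dplyr::count(cluster_type)
#> # A tibble: 3 × 2
#>   cluster_type     n
#>   <chr>        <int>
#> 1 shared           2
#> 2 singleton        2
#> 3 specific         2

cooccurrence_edges(toy$clustering)
#> # A tibble: 3 × 3
#>   from  to    weight
#>   <chr> <chr>  <int>
#> 1 A     B          3
#> 2 A     C          2
#> 3 B     C          2
```

`OG0` and `OG4` contain exactly one protein from each of the three
proteomes, so they are the strict single-copy orthologs. Under the `host`
attribute (`A`,`B` = human, `C` = other), the two-proteome cluster `OG1`
becomes host-*specific* even though it spans two proteomes, while the two
universal clusters stay *shared*. Proteomes `A` and `B` co-occur in three
clusters; excluding the two universal clusters leaves weight 1.

A complete run over files on disk — one output directory per attribute,
with cluster types, level summaries, rarefaction curves, representation
tests, SCO lists, representative annotation, and tree outputs — is a single
call:

```r
run_analysis(
  clustering_path = "Orthogroups.txt", config_path = "config.csv",
  sequence_ids_path = "SequenceIDs.txt",
  annotation_path = "annotations.tsv", fasta_paths = Sys.glob("fasta/*.faa"),
  tree_path = "tree.nwk", outgroups = c("CELEG", "CBRIG"),
  out_dir = "kinfin_out"
)
```

A thin command-line wrapper with the same options is installed at
`inst/scripts/clusterkin.R` (subcommands `analyse`, `fixture`, `goi`).

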