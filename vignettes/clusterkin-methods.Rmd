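---
title: "Methods and design of clusterkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of clusterkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterkin)
```

`clusterkin` takes a finished protein orthology clustering — the output of
tools such as OrthoFinder or OrthoMCL — and analyses it under arbitrary
groupings of the input proteomes. This vignette explains the statistical
procedures, the tunable parameters, the numerical choices, and what the
synthetic data generator does and does not emulate.

## Data model

All analyses operate on three tidy tables:

* a **clustering** (`cluster_id`, `proteome_id`, `protein_id`; one row per
  member protein; no protein in two clusters),
* a **config** of proteome attributes, each attribute partitioning the
  proteomes into levels ("taxon sets"); the reserved attributes `all` (one
  set of everything) and `TAXON` (one set per proteome) are always present,
* an **annotation** table (`protein_id`, `source`, `term_id`,
  `description`) produced from InterProScan TSV, with the `analysis` column
  passed through verbatim as namespaces and two synthesized namespaces,
  `IPR` (InterPro accessions) and `GO` (split on `|`). We deliberately do
  not whitelist analyses: PRINTS, PANTHER and the like flow through under
  their own names, because discarding them silently would surprise users
  who annotated with a full InterProScan configuration.

Trees are `ape::phylo` objects rooted on a user-specified outgroup, with
internal nodes labeled `n0..nK` in preorder from the root. The labels are a
presentation convention: any published node numbering is reproduced only
when the same topology and outgroup are supplied.

## Cluster typing

For each attribute, a cluster is `singleton` (size 1), `specific` (size ≥ 2
and all members from one level) or `shared` (members from ≥ 2 levels).
Note that *specific* is defined on taxon sets, not proteomes: a two-protein
cluster drawn from two proteomes of the same level is specific to that
level. The three types partition the clusters, and member proteins are
conserved across the partition — both properties are enforced by tests.

## Single-copy orthologs

Strict SCOs have exactly one protein from every proteome. Because assembly
and annotation artifacts erode this set as more proteomes are added, a
fuzzy relaxation is provided with four parameters: `target_count` (default
1), `target_fraction` (fraction of proteomes required at exactly the target
count; default 0.75), and `min_count`/`max_count` bounds for the remaining
proteomes (defaults 1 and 2; `min_count = 0` explicitly permits absence,
the default requires presence in every proteome). The fraction comparison
is performed by integer cross-multiplication (`n_at_target ≥ ⌈f·n⌉`), so
boundary cases such as 2/3 against 0.6 never depend on floating-point
rounding. The defaults are the package's own choice of a mild relaxation;
they are deliberately explicit parameters because the appropriate values
depend on the divergence of the taxa being clustered.

## Rarefaction

For each taxon set, proteomes are sampled in random order (uniform
permutations, default 30 repetitions) and the cumulative number of distinct
*nonsingleton* clusters is recorded after each addition. Singletons are
excluded because they carry no co-occurrence information and would reduce
the curve to a proteome-size effect. The final point of every repetition is
sampling-free — it equals the number of nonsingleton clusters with at least
one member in the set — which the tests exploit as an identity. Sampling is
seed-controlled and the caller's RNG state is restored afterwards.

## Representation tests

For two taxon sets A and B, every cluster containing at least one protein
from each set is tested for count nonhomogeneity. The count vectors cover
*all* proteomes of each set, including zeros for members absent from the
cluster: a cluster present in every A proteome but missing from half of B
is exactly the depletion signal the test should see. The default test is
the two-sided Mann–Whitney *U*. With `min(n1, n2) ≤ 8` the p-value is
computed by full enumeration of all `C(n1+n2, n1)` group assignments of the
pooled counts (midranks for ties; extremeness measured as `|U − n1·n2/2|`);
larger samples use the normal approximation with tie and continuity
correction. On tie-free samples of size 8 the two routes agree to within
0.02; with heavy ties the approximation can deviate substantially, which is
why small samples — the common case, since "samples" are proteomes — are
always enumerated. Welch and Student *t*-tests are available as
alternatives; when both groups are constant and equal the p-value is 1, and
when both are constant but unequal the *t* statistic is undefined and `NA`
is returned.

P-values are reported raw, with **no multiple-testing correction**: the
volcano plot draws guide lines at p = 0.05 and 0.01 and at `|log2fc| = 1`
and the 95th percentile of `|log2fc|` (linear interpolation). With tens of
thousands of clusters, users requiring family-wise control should apply
`p.adjust` downstream; the raw presentation mirrors the exploratory intent
of the analysis, and is documented here prominently for that reason. With
fewer than two proteomes on either side no test is attempted (`NA`).

## Cluster sizes and co-occurrence

The cluster-size histogram is reported per size and per number of
contributing proteomes. A reference power law `n(s) = C·s^(−γ)` is fitted
by ordinary least squares on the log-log histogram over nonzero bins; this
is a visual reference, not an inferential power-law test, which is why no
maximum-likelihood estimator or goodness-of-fit machinery is used. A local
excess at size equal to the number of proteomes is the expected signature
of single-copy orthologs. The co-occurrence network weights proteome pairs
by the number of clusters in which both occur; universal clusters (members
from every proteome) can be excluded, since they contribute a constant to
every edge and mask structure.

## Dollo synapomorphies

Under Dollo parsimony a gene family arises once and may be lost many
times. A cluster is therefore synapomorphic for the branch leading to a
node when (a) only proteomes under that node are members and (b) every
child subtree of the node contributes at least one member. These conditions
pin the node uniquely: the implementation assigns the MRCA of the member
proteomes and verifies child support, while the tests check the rule
itself by exhaustive search over all nodes of random small trees. Because
losses are free, coverage classes temper the headline counts:
`complete_presence` (all leaves under the node present),
`partial_absence` (coverage ≥ `node_taxon_cov`, default 0.75), and
`below_threshold` (assigned by the rule but under the reporting threshold).
The third class is written to the detailed output and excluded from
summary counts — whether to assign such clusters at all is genuinely open,
and keeping them visible but fenced off preserves both the parsimony logic
and a conservative headline. Clusters containing proteomes absent from the
tree indicate a config/tree mismatch and are excluded with a warning rather
than silently.

## Representative annotation

A term is representative of a cluster when it passes `domain_taxon_cov`
(fraction of the cluster's proteomes with ≥ 1 annotated protein) and
`domain_protein_cov` (fraction of the cluster's proteins annotated). Both
default to 0.75, chosen to parallel the 75% node-coverage convention of the
synapomorphy module; there is no community standard for these thresholds,
so they are prominent, overridable parameters. Raising either threshold can
only remove terms — a monotonicity property the tests verify. Term entropy
within clusters uses incidence weights: with `c_d` proteins carrying term
`d`, `p_d = c_d / Σc_d` and `H = −Σ p_d log2 p_d` bits. Base 2 keeps the
uniform two-term cluster at exactly 1 bit and makes values comparable
across cluster sizes; clusters with no annotation in a namespace report
`NA` rather than 0, distinguishing "unannotated" from "homogeneous". The
same distinction motivates reporting the standard deviation of lengths in
singleton clusters as `NA` (undefined) rather than 0 (degenerate); length
SD is the sample (n−1) estimator.

## Gene-of-interest lookup

Query IDs match proteins exactly or as a gene-ID prefix followed by an
isoform separator (`.`, `-`, `_t` — the conventions of common gene-model
naming schemes). The matched protein set is returned alongside the report
so users can audit the prefix expansion; unmatched IDs are reported, never
fatal.

## The synthetic data generator

`generate_bundle()` produces a complete, internally consistent input
bundle — clustering, SequenceIDs, config (with a `clade` attribute from the
root split and TaxIDs), per-proteome FASTAs, InterProScan-dialect
annotation, Newick tree and a miniature taxdump — together with a manifest
of expected results computed at generation time by direct application of
the defining rules to the known memberships (not by calling the analysis
functions). Defaults are a scaled-down emulation of a multi-species
clustering: 8 proteomes on a random binary topology, 8 strict SCOs, 4
fuzzy-only clusters (25% of proteomes duplicated), 2 complete-presence
synapomorphies per non-root node, per-proteome private clusters and
singletons, and 20 random shared clusters whose synapomorphy status the
generator derives from its own tree records. Protein lengths are normal
(mean 300 aa, SD 100, truncated at 50) — typical of eukaryotic proteomes;
sequences are random residue strings. The same problem size is used by the
acceptance script; it keeps a full pipeline run under a second while
exercising every code path.

What the generator does **not** emulate: sequence similarity (clusters are
defined by construction, not inferred), realistic gene-family size
distributions (the implanted mixture is stylized), annotation error, or
fragmented gene models. Passing tests on generated bundles therefore
demonstrate that the bookkeeping, classification, statistics and
phylogenetic logic are correct on known ground truth — not that any
upstream clustering is biologically sound.

## Degenerate inputs and tie-breaks

* Representative terms are ranked by protein coverage, then taxon
  coverage, then term ID — fully deterministic output ordering.
* A histogram with a single distinct size yields no power-law fit
  (`available = FALSE`) instead of an error.
* Cluster files may reference internal tokens (`0_0`) or raw protein IDs;
  the dialect is auto-detected from the first member, because OrthoMCL
  emits raw IDs.
* Identical seeds reproduce every output byte-for-byte; all parsers report
  file and line on failure.

## Limitations

The package consumes clusterings; it does not run BLAST, OrthoFinder or
InterProScan, nor align or filter sequences (isoform filtering is a
recommended preprocessing step, not a feature). Graph rendering is left to
dedicated tools — the GraphML export is the interface. Synapomorphy
inference is single-gain Dollo only; per-branch loss enumeration and
general ancestral-state reconstruction are out of scope.
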