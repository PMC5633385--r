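# independent brute-force oracles used across test files

# fuzzy single-copy predicate applied directly to a copy-count vector over
# all proteomes (zeros for absent ones)
fuzzy_predicate <- function(counts_full, target_count, target_fraction,
                            min_count, max_count) {
  all(counts_full >= min_count) &&
    all(counts_full <= max_count) &&
    sum(counts_full == target_count) / length(counts_full) >= target_fraction - 1e-12
}

# Dollo synapomorphy rule checked against every internal node of a tree:
# all member proteomes under the node, and every child subtree represented
dollo_oracle_nodes <- function(tree, members) {
  under <- leaves_under(tree)
  hits <- character(0)
  for (lab in names(under)) {
    if (!all(members %in% under[[lab]])) next
    kids <- clusterkin:::children_leaf_sets(tree, lab)
    if (all(vapply(kids, function(k) any(members %in% k), logical(1)))) {
      hits <- c(hits, lab)
    }
  }
  hits
}

# one-cluster clustering tibble from a proteome presence profile
profile_clustering <- function(members, copies = NULL) {
  copies <- copies %||% stats::setNames(rep(1L, length(members)), members)
  tibble::tibble(
    cluster_id = "OGX",
    proteome_id = rep(names(copies), copies),
    protein_id = paste0(rep(names(copies), copies), "_p",
                        unlist(lapply(copies, seq_len)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
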