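#' Dollo-parsimony synapomorphic clusters on a tree
#'
#' Under Dollo parsimony a gene family is gained once and lost freely, so a
#' cluster is synapomorphic for the branch leading to a node when (a) all its
#' member proteomes lie under that node and (b) every child subtree of the
#' node contributes at least one member. These two conditions pin the node to
#' the MRCA of the member proteomes, which is how the search is implemented;
#' the rule itself is the specification. Because losses are unpenalised,
#' synapomorphies are graded by taxon coverage (member proteomes / leaves
#' under the node): `complete_presence` at coverage 1, `partial_absence` at
#' `node_taxon_cov <= coverage < 1`, and `below_threshold` otherwise
#' (reported, but conventionally excluded from headline counts). Singleton
#' and single-proteome clusters are apomorphies, not synapomorphies, and are
#' skipped (see [list_apomorphies()]).
#'
#' @param clustering A clustering tibble.
#' @param tree A labeled rooted tree from [read_tree_topology()]; its leaves
#'   must cover every proteome in the clustering (offending clusters are
#'   dropped with a warning).
#' @param node_taxon_cov Coverage threshold separating `partial_absence` from
#'   `below_threshold` (default 0.75).
#' @return A tibble with `cluster_id`, `node`, `coverage`,
#'   `n_proteomes_cluster`, `n_leaves_node`, `class`.
#' @export
infer_synapomorphies <- function(clustering, tree, node_taxon_cov = 0.75) {
  assert_clustering(clustering)
  if (node_taxon_cov < 0 || node_taxon_cov > 1) {
    abort("node_taxon_cov must be in [0, 1]")
  }
  pres <- distinct(clustering, .data$cluster_id, .data$proteome_id)
  off_tree <- setdiff(unique(pres$proteome_id), tree$tip.label)
  if (length(off_tree) > 0) {
    warn(sprintf("proteome(s) not in tree, their clusters are excluded: %s",
                 paste(off_tree, collapse = ", ")))
    bad <- unique(pres$cluster_id[pres$proteome_id %in% off_tree])
    pres <- filter(pres, !.data$cluster_id %in% bad)
  }
  multi <- pres |>
    group_by(.data$cluster_id) |>
    summarise(proteomes = list(unique(.data$proteome_id)), .groups = "drop") |>
    filter(lengths(.data$proteomes) >= 2)
  if (nrow(multi) == 0) {
    return(tibble(cluster_id = character(0), node = character(0),
                  coverage = double(0), n_proteomes_cluster = integer(0),
                  n_leaves_node = integer(0), class = character(0)))
  }
  under <- leaves_under(tree)
  kids <- lapply(names(under), function(nl) children_leaf_sets(tree, nl))
  names(kids) <- names(under)

  rows <- purrr::pmap(multi, function(cluster_id, proteomes) {
    node <- mrca_label(tree, proteomes)
    if (is.na(node)) return(NULL)
    # at the MRCA both rule conditions hold by construction; assert anyway
    if (!all(proteomes %in% under[[node]])) return(NULL)
    if (!all(vapply(kids[[node]], function(k) any(proteomes %in% k), logical(1)))) {
      return(NULL)
    }
    cov <- length(proteomes) / length(under[[node]])
    tibble(
      cluster_id = cluster_id, node = node, coverage = cov,
      n_proteomes_cluster = length(proteomes),
      n_leaves_node = length(under[[node]]),
      class = if (cov == 1) "complete_presence"
              else if (cov >= node_taxon_cov) "partial_absence"
              else "below_threshold"
    )
  })
  ids <- keep_cluster_order(clustering)
  bind_rows(rows) |> arrange(match(.data$cluster_id, ids))
}

#' Per-proteome apomorphic clusters
#'
#' Apomorphies are proteome-private clusters: `singleton` (one protein) and
#' `nonsingleton` (two or more proteins, all from one proteome). Together
#' with [infer_synapomorphies()] these cover the cluster types of the
#' `TAXON` attribute.
#'
#' @param clustering A clustering tibble.
#' @return A tibble with `proteome_id`, `cluster_id`, `apomorphy_type`.
#' @export
list_apomorphies <- function(clustering) {
  assert_clustering(clustering)
  cluster_summary(clustering) |>
    filter(.data$proteome_count == 1) |>
    left_join(distinct(clustering, .data$cluster_id, .data$proteome_id),
              by = "cluster_id") |>
    mutate(apomorphy_type = if_else(.data$size == 1, "singleton", "nonsingleton")) |>
    select("proteome_id", "cluster_id", "apomorphy_type") |>
    arrange(.data$proteome_id, .data$cluster_id)
}

#' Node-level summary of synapomorphies and their annotation
#'
#' For each internal node, counts complete-presence and partial-absence
#' synapomorphic clusters and, when annotations are given, the fraction of
#' them with at least one representative term at the domain coverage
#' thresholds. Nodes without qualifying synapomorphies get `NA` fractions.
#'
#' @param synapomorphies Output of [infer_synapomorphies()].
#' @param clustering A clustering tibble.
#' @param tree The tree used for inference.
#' @param annotations Optional annotation tibble.
#' @param domain_taxon_cov,domain_protein_cov Thresholds for
#'   [representative_annotation()].
#' @param namespace Optional namespace restriction (e.g. `"IPR"`).
#' @return A tibble with one row per internal node: `node`,
#'   `n_complete_presence`, `n_partial_absence`, `n_below_threshold`,
#'   `n_synapomorphies` (complete + partial), and `fraction_annotated`.
#' @export
node_annotation_summary <- function(synapomorphies, clustering, tree,
                                    annotations = NULL,
                                    domain_taxon_cov = 0.75,
                                    domain_protein_cov = 0.75,
                                    namespace = NULL) {
  nodes <- names(leaves_under(tree))
  counts <- synapomorphies |>
    count(.data$node, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  for (col in c("complete_presence", "partial_absence", "below_threshold")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- tibble(node = nodes) |>
    left_join(counts, by = "node") |>
    mutate(across(c("complete_presence", "partial_absence", "below_threshold"),
                  \(x) tidyr::replace_na(x, 0L))) |>
    rename(n_complete_presence = "complete_presence",
           n_partial_absence = "partial_absence",
           n_below_threshold = "below_threshold") |>
    mutate(n_synapomorphies = .data$n_complete_presence + .data$n_partial_absence)

  if (is.null(annotations)) {
    out$fraction_annotated <- NA_real_
    return(out)
  }
  headline <- filter(synapomorphies, .data$class != "below_threshold")
  annotated_ids <- character(0)
  if (nrow(headline) > 0) {
    rep_ann <- representative_annotation(
      filter(clustering, .data$cluster_id %in% headline$cluster_id),
      annotations, domain_taxon_cov, domain_protein_cov, namespace
    )
    annotated_ids <- unique(rep_ann$cluster_id)
  }
  per_node <- headline |>
    group_by(.data$node) |>
    summarise(
      fraction_annotated = mean(.data$cluster_id %in% annotated_ids),
      .groups = "drop"
    )
  out |>
    left_join(per_node, by = "node") |>
    mutate(fraction_annotated = if_else(.data$n_synapomorphies == 0,
                                        NA_real_, .data$fraction_annotated))
}
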