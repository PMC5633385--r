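#' Read and root a Newick tree topology
#'
#' Reads a Newick tree whose leaves are proteome IDs, roots it on the given
#' outgroup split, and labels internal nodes `n0..nK` in preorder from the
#' root. Branch lengths, if any, are ignored: only the topology is used.
#'
#' @param path Path to a Newick file, or a Newick string (detected by a
#'   trailing `;`).
#' @param outgroups Character vector of leaf labels to root on. `NULL` keeps
#'   the tree as read (it must then already be rooted).
#' @param proteomes Optional character vector (e.g. `config$proteome_id`);
#'   when given, every leaf label must be one of these.
#' @return An [ape::phylo] object with `node.label` set to `n0..nK`.
#' @examples
#' tr <- read_tree_topology("((A,B),C);", outgroups = "C")
#' tr$node.label
#' @export
read_tree_topology <- function(path, outgroups = NULL, proteomes = NULL) {
  if (grepl(";\\s*$", path)) {
    phy <- ape::read.tree(text = path)
  } else {
    phy <- ape::read.tree(path)
  }
  if (is.null(phy)) {
    abort("could not parse Newick input", class = "clusterkin_parse_error")
  }
  if (!is.null(proteomes)) {
    unknown <- setdiff(phy$tip.label, proteomes)
    if (length(unknown) > 0) {
      abort(sprintf("tree leaf not in attribute config: %s",
                    paste(unknown, collapse = ", ")),
            class = "clusterkin_parse_error")
    }
  }
  if (!is.null(outgroups)) {
    missing_og <- setdiff(outgroups, phy$tip.label)
    if (length(missing_og) > 0) {
      abort(sprintf("outgroup not found in tree: %s", paste(missing_og, collapse = ", ")),
            class = "clusterkin_parse_error")
    }
    phy <- ape::root(phy, outgroup = outgroups, resolve.root = TRUE)
  } else if (!ape::is.rooted(phy)) {
    abort("tree is unrooted and no outgroups were given", class = "clusterkin_parse_error")
  }
  phy$edge.length <- NULL
  phy <- stats::reorder(phy, "cladewise")
  internal_order <- unique(phy$edge[, 1]) # parents appear in preorder
  lab <- character(phy$Nnode)
  lab[internal_order - ape::Ntip(phy)] <- sprintf("n%d", seq_along(internal_order) - 1L)
  phy$node.label <- lab
  phy
}

# internal node numbers in preorder (root first)
internal_nodes_preorder <- function(phy) {
  unique(stats::reorder(phy, "cladewise")$edge[, 1])
}

#' Leaf sets under each internal node
#'
#' @param phy A labeled tree from [read_tree_topology()].
#' @return Named list mapping internal node label to the character vector of
#'   leaf (proteome) labels under that node.
#' @export
leaves_under <- function(phy) {
  ntip <- ape::Ntip(phy)
  nodes <- internal_nodes_preorder(phy)
  tips <- phangorn::Descendants(phy, nodes, type = "tips")
  out <- lapply(tips, function(i) phy$tip.label[i])
  names(out) <- phy$node.label[nodes - ntip]
  out
}

# leaf sets of each child subtree of an internal node (by node label)
children_leaf_sets <- function(phy, node_label) {
  ntip <- ape::Ntip(phy)
  node <- ntip + match(node_label, phy$node.label)
  if (is.na(node)) abort(sprintf("unknown node label '%s'", node_label))
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  lapply(kids, function(k) {
    if (k <= ntip) phy$tip.label[k] else phy$tip.label[phangorn::Descendants(phy, k, "tips")[[1]]]
  })
}

# label of the MRCA of a set of leaves (label of the leaf's parent-free case:
# a single leaf has no internal MRCA -> NA)
mrca_label <- function(phy, leaves) {
  ntip <- ape::Ntip(phy)
  idx <- match(leaves, phy$tip.label)
  if (anyNA(idx)) return(NA_character_)
  if (length(unique(idx)) == 1) return(NA_character_)
  node <- ape::getMRCA(phy, unique(idx))
  phy$node.label[node - ntip]
}
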