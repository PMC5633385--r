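#' Proteome co-occurrence network edges
#'
#' Builds the weighted undirected graph whose nodes are proteomes and whose
#' edge weights count the clusters in which two proteomes co-occur (each with
#' at least one member protein). Universal clusters — those containing members
#' from every proteome — dominate the weights and can be excluded to expose
#' finer structure.
#'
#' @param clustering A clustering tibble.
#' @param exclude_universal Drop clusters present in all proteomes.
#' @param proteomes Optional full proteome list (defines "universal" and the
#'   node set of [write_cooccurrence_graphml()]).
#' @return A tibble with columns `from`, `to` (`from < to` lexically) and
#'   `weight`.
#' @export
cooccurrence_edges <- function(clustering, exclude_universal = FALSE, proteomes = NULL) {
  assert_clustering(clustering)
  proteomes <- proteomes %||% unique(clustering$proteome_id)
  pres <- distinct(clustering, .data$cluster_id, .data$proteome_id)
  if (exclude_universal) {
    universal <- pres |>
      count(.data$cluster_id) |>
      filter(.data$n == length(proteomes)) |>
      pull("cluster_id")
    pres <- filter(pres, !.data$cluster_id %in% universal)
  }
  by_cluster <- split(pres$proteome_id, pres$cluster_id)
  pairs <- lapply(by_cluster, function(p) {
    if (length(p) < 2) return(NULL)
    p <- sort(p)
    cmb <- combn(p, 2)
    tibble(from = cmb[1, ], to = cmb[2, ])
  })
  edges <- bind_rows(pairs)
  if (nrow(edges) == 0) {
    return(tibble(from = character(0), to = character(0), weight = integer(0)))
  }
  edges |>
    count(.data$from, .data$to, name = "weight") |>
    arrange(.data$from, .data$to)
}

#' Write a co-occurrence network to GraphML
#'
#' @param edges Edge tibble from [cooccurrence_edges()].
#' @param path Output `.graphml` path.
#' @param proteomes Optional node list; isolated proteomes are kept as
#'   unconnected nodes.
#' @return `path`, invisibly.
#' @export
write_cooccurrence_graphml <- function(edges, path, proteomes = NULL) {
  vertices <- if (is.null(proteomes)) NULL else data.frame(name = proteomes)
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                     vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
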