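#' Per-cluster annotation term coverages
#'
#' For every annotation term seen on a member of a cluster, computes
#' `protein_cov` (fraction of member proteins carrying the term) and
#' `taxon_cov` (fraction of member proteomes with at least one carrying
#' protein). Terms absent from a cluster are not listed.
#'
#' @param clustering A clustering tibble.
#' @param annotations Annotation tibble from [read_interproscan()].
#' @param namespace Optional single namespace to restrict to (e.g. `"IPR"`).
#' @return A tibble with `cluster_id`, `source`, `term_id`, `description`,
#'   `protein_count`, `proteome_count`, `protein_cov`, `taxon_cov`.
#' @export
term_coverages <- function(clustering, annotations, namespace = NULL) {
  assert_clustering(clustering)
  ann <- annotations
  if (!is.null(namespace)) ann <- filter(ann, .data$source %in% namespace)
  sizes <- cluster_summary(clustering) |>
    rename(cluster_size = "size", cluster_proteomes = "proteome_count")
  clustering |>
    inner_join(ann, by = "protein_id", relationship = "many-to-many") |>
    distinct(.data$cluster_id, .data$proteome_id, .data$protein_id,
             .data$source, .data$term_id, .data$description) |>
    group_by(.data$cluster_id, .data$source, .data$term_id) |>
    summarise(
      description = first(.data$description[nzchar(.data$description)], default = ""),
      protein_count = n_distinct(.data$protein_id),
      proteome_count = n_distinct(.data$proteome_id),
      .groups = "drop"
    ) |>
    left_join(sizes, by = "cluster_id") |>
    mutate(
      protein_cov = .data$protein_count / .data$cluster_size,
      taxon_cov = .data$proteome_count / .data$cluster_proteomes
    ) |>
    select(-"cluster_size", -"cluster_proteomes")
}

#' Representative functional annotation of clusters
#'
#' No universal standard exists for lifting per-protein annotation to the
#' cluster level; here a term is representative of a cluster when it passes
#' two coverage thresholds: `domain_taxon_cov` (minimum fraction of the
#' cluster's proteomes with at least one annotated protein) and
#' `domain_protein_cov` (minimum fraction of the cluster's proteins
#' annotated). Surviving terms are ranked by protein coverage, then taxon
#' coverage, then term ID.
#'
#' @inheritParams term_coverages
#' @param domain_taxon_cov,domain_protein_cov Coverage thresholds in `[0, 1]`
#'   (defaults 0.75, mirroring the 75% node-coverage convention of
#'   [infer_synapomorphies()]).
#' @return A tibble like [term_coverages()], filtered and ranked; clusters
#'   with no row are unannotated at these thresholds.
#' @export
representative_annotation <- function(clustering, annotations,
                                      domain_taxon_cov = 0.75,
                                      domain_protein_cov = 0.75,
                                      namespace = NULL) {
  if (domain_taxon_cov < 0 || domain_taxon_cov > 1 ||
      domain_protein_cov < 0 || domain_protein_cov > 1) {
    abort("coverage thresholds must be in [0, 1]")
  }
  term_coverages(clustering, annotations, namespace) |>
    filter(.data$taxon_cov >= domain_taxon_cov,
           .data$protein_cov >= domain_protein_cov) |>
    arrange(.data$cluster_id, desc(.data$protein_cov), desc(.data$taxon_cov),
            .data$term_id)
}

#' Report clusters containing genes of interest
#'
#' Looks up a list of protein or gene IDs in the clustering and reports, for
#' each hit cluster, per-proteome protein counts, which query IDs hit it, and
#' (when annotations are given) its representative functional annotation. A
#' gene ID matches a protein ID exactly or as a prefix followed by one of the
#' isoform separators `.`, `-`, `_t`.
#'
#' @param clustering A clustering tibble.
#' @param ids Character vector of query protein/gene IDs.
#' @param annotations Optional annotation tibble.
#' @param domain_taxon_cov,domain_protein_cov Thresholds passed to
#'   [representative_annotation()].
#' @return A tibble with one row per hit cluster: `cluster_id`, `hits`
#'   (matching query IDs, list column), `matched_proteins` (list column),
#'   per-proteome count columns, and `representative_terms` when annotations
#'   were supplied. Query IDs matching nothing are recorded in the
#'   `"unmatched_ids"` attribute.
#' @export
genes_of_interest_report <- function(clustering, ids, annotations = NULL,
                                     domain_taxon_cov = 0.75,
                                     domain_protein_cov = 0.75) {
  assert_clustering(clustering)
  if (length(ids) == 0) abort("`ids` must be nonempty")
  proteins <- unique(clustering$protein_id)
  match_one <- function(id) {
    hits <- proteins[proteins == id |
                       startsWith(proteins, paste0(id, ".")) |
                       startsWith(proteins, paste0(id, "-")) |
                       startsWith(proteins, paste0(id, "_t"))]
    hits
  }
  matches <- lapply(ids, match_one)
  names(matches) <- ids
  unmatched <- ids[lengths(matches) == 0]
  hit_tbl <- tibble(
    query = rep(names(matches), lengths(matches)),
    protein_id = unlist(matches, use.names = FALSE)
  )
  if (nrow(hit_tbl) == 0) {
    out <- tibble(cluster_id = character(0))
    attr(out, "unmatched_ids") <- unmatched
    return(out)
  }
  hit_clusters <- clustering |>
    inner_join(hit_tbl, by = "protein_id") |>
    group_by(.data$cluster_id) |>
    summarise(
      hits = list(sort(unique(.data$query))),
      matched_proteins = list(sort(unique(.data$protein_id))),
      .groups = "drop"
    )
  counts <- clustering |>
    filter(.data$cluster_id %in% hit_clusters$cluster_id) |>
    count(.data$cluster_id, .data$proteome_id) |>
    tidyr::pivot_wider(names_from = "proteome_id", values_from = "n", values_fill = 0L)
  out <- left_join(hit_clusters, counts, by = "cluster_id")
  if (!is.null(annotations)) {
    rep_ann <- representative_annotation(
      filter(clustering, .data$cluster_id %in% out$cluster_id),
      annotations, domain_taxon_cov, domain_protein_cov
    ) |>
      group_by(.data$cluster_id) |>
      summarise(representative_terms = list(.data$term_id), .groups = "drop")
    out <- left_join(out, rep_ann, by = "cluster_id")
  }
  attr(out, "unmatched_ids") <- unmatched
  out
}
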