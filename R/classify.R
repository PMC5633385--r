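#' Per-cluster size summary
#'
#' @param clustering A clustering tibble (`cluster_id`, `proteome_id`,
#'   `protein_id`).
#' @return A tibble with `cluster_id`, `size` (protein count) and
#'   `proteome_count`, in first-appearance cluster order.
#' @export
cluster_summary <- function(clustering) {
  assert_clustering(clustering)
  ids <- keep_cluster_order(clustering)
  clustering |>
    group_by(.data$cluster_id) |>
    summarise(size = n(), proteome_count = n_distinct(.data$proteome_id), .groups = "drop") |>
    arrange(match(.data$cluster_id, ids))
}

#' Classify clusters against the taxon sets of one attribute
#'
#' Every cluster receives exactly one type per attribute:
#' * `singleton` — the cluster contains a single protein;
#' * `specific` — two or more proteins, all from proteomes of one level;
#' * `shared` — proteins from two or more levels.
#'
#' @param clustering A clustering tibble.
#' @param config A config tibble from [read_attribute_config()].
#' @param attribute Attribute name.
#' @return A tibble with `cluster_id`, `attribute`, `cluster_type`,
#'   `n_levels`, and `covered_levels` (list column of level names with at
#'   least one member protein).
#' @export
classify_clusters <- function(clustering, config, attribute) {
  assert_clustering(clustering)
  sets <- taxon_sets(config, attribute)
  unknown <- setdiff(unique(clustering$proteome_id), sets$proteome_id)
  if (length(unknown) > 0) {
    abort(sprintf("proteome(s) in clustering but not in config: %s",
                  paste(unknown, collapse = ", ")))
  }
  ids <- keep_cluster_order(clustering)
  joined <- left_join(clustering, sets, by = "proteome_id")
  joined |>
    group_by(.data$cluster_id) |>
    summarise(
      size = n(),
      covered_levels = list(sort(unique(.data$level))),
      .groups = "drop"
    ) |>
    mutate(
      attribute = attribute,
      n_levels = lengths(.data$covered_levels),
      cluster_type = dplyr::case_when(
        size == 1 ~ "singleton",
        n_levels == 1 ~ "specific",
        TRUE ~ "shared"
      )
    ) |>
    arrange(match(.data$cluster_id, ids)) |>
    select("cluster_id", "attribute", "cluster_type", "n_levels", "covered_levels")
}

#' Cluster-by-level protein count matrix
#'
#' @inheritParams classify_clusters
#' @return A tibble with `cluster_id` and one integer column per level of the
#'   attribute (protein counts; zero when absent). Row order follows the
#'   clustering; column order follows level order of first appearance in the
#'   config.
#' @export
cluster_level_counts <- function(clustering, config, attribute) {
  assert_clustering(clustering)
  sets <- taxon_sets(config, attribute)
  ids <- keep_cluster_order(clustering)
  level_order <- unique(sets$level)
  wide <- clustering |>
    left_join(sets, by = "proteome_id") |>
    count(.data$cluster_id, .data$level) |>
    tidyr::pivot_wider(names_from = "level", values_from = "n", values_fill = 0L)
  missing_levels <- setdiff(level_order, names(wide))
  for (lv in missing_levels) wide[[lv]] <- 0L
  wide |>
    arrange(match(.data$cluster_id, ids)) |>
    select(dplyr::all_of(c("cluster_id", level_order)))
}

#' Cluster-by-level presence matrix
#'
#' @inheritParams classify_clusters
#' @return Like [cluster_level_counts()] but with logical presence values.
#' @export
cluster_level_presence <- function(clustering, config, attribute) {
  counts <- cluster_level_counts(clustering, config, attribute)
  counts |> mutate(across(-"cluster_id", \(x) x > 0))
}

#' Per-level summary of cluster types and protein counts
#'
#' For each level of an attribute, tallies the clusters of each type in which
#' the level is present, and the proteins that level contributes.
#'
#' @inheritParams classify_clusters
#' @return A tibble with one row per level: `n_proteomes`, cluster counts
#'   (`clusters_total`, `clusters_singleton`, `clusters_specific`,
#'   `clusters_shared`) and protein counts (`proteins_total`,
#'   `proteins_singleton`, `proteins_specific`, `proteins_shared`).
#' @export
level_summary <- function(clustering, config, attribute) {
  sets <- taxon_sets(config, attribute)
  types <- classify_clusters(clustering, config, attribute)
  per_level <- clustering |>
    left_join(sets, by = "proteome_id") |>
    left_join(select(types, "cluster_id", "cluster_type"), by = "cluster_id") |>
    group_by(.data$level, .data$cluster_type) |>
    summarise(
      clusters = n_distinct(.data$cluster_id),
      proteins = n(),
      .groups = "drop"
    )
  wide <- per_level |>
    tidyr::pivot_wider(
      names_from = "cluster_type", values_from = c("clusters", "proteins"),
      values_fill = 0L
    )
  for (col in c("clusters_singleton", "clusters_specific", "clusters_shared",
                "proteins_singleton", "proteins_specific", "proteins_shared")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  sizes <- sets |> count(.data$level, name = "n_proteomes")
  wide |>
    left_join(sizes, by = "level") |>
    mutate(
      clusters_total = .data$clusters_singleton + .data$clusters_specific + .data$clusters_shared,
      proteins_total = .data$proteins_singleton + .data$proteins_specific + .data$proteins_shared
    ) |>
    select("level", "n_proteomes", "clusters_total", "clusters_singleton",
           "clusters_specific", "clusters_shared", "proteins_total",
           "proteins_singleton", "proteins_specific", "proteins_shared") |>
    arrange(match(.data$level, unique(sets$level)))
}
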