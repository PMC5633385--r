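#' Strict single-copy ortholog clusters
#'
#' A true single-copy ortholog (SCO) cluster contains exactly one protein
#' from every proteome in the analysis.
#'
#' @param clustering A clustering tibble.
#' @param proteomes Optional character vector of all proteome IDs; defaults
#'   to the proteomes observed in the clustering. Supply the config's
#'   proteome list when some proteomes might contribute no clustered protein.
#' @return A tibble with column `cluster_id`, in clustering order.
#' @export
find_true_scos <- function(clustering, proteomes = NULL) {
  assert_clustering(clustering)
  proteomes <- proteomes %||% unique(clustering$proteome_id)
  n <- length(proteomes)
  cluster_summary(clustering) |>
    filter(.data$size == n, .data$proteome_count == n) |>
    select("cluster_id")
}

#' Fuzzy single-copy ortholog clusters
#'
#' Relaxed SCO detection for clusterings of distant taxa, where stochastic
#' absence and duplication erode the strict single-copy set. A cluster
#' qualifies when (a) every proteome's copy count `c` lies in
#' `[min_count, max_count]` (with `min_count >= 1` this forces presence in
#' every proteome; `min_count = 0` permits absence), and (b) the fraction of
#' proteomes with exactly `target_count` copies is at least
#' `target_fraction`. The fraction comparison is exact (integer
#' cross-multiplication), so boundary cases like 2/3 >= 0.6 never depend on
#' floating-point rounding.
#'
#' @param clustering A clustering tibble.
#' @param target_count Target copies per proteome (default 1).
#' @param target_fraction Minimum fraction of proteomes at the target count.
#' @param min_count,max_count Copy-count bounds for proteomes off target.
#' @param proteomes Optional full proteome list (see [find_true_scos()]).
#' @return A tibble with column `cluster_id`.
#' @export
find_fuzzy_scos <- function(clustering, target_count = 1L, target_fraction = 0.75,
                            min_count = 1L, max_count = 2L, proteomes = NULL) {
  assert_clustering(clustering)
  if (min_count > target_count || target_count > max_count) {
    abort("fuzzy parameters must satisfy min_count <= target_count <= max_count")
  }
  if (target_fraction < 0 || target_fraction > 1) {
    abort("target_fraction must be in [0, 1]")
  }
  proteomes <- proteomes %||% unique(clustering$proteome_id)
  n <- length(proteomes)
  ids <- keep_cluster_order(clustering)

  counts <- clustering |>
    count(.data$cluster_id, .data$proteome_id, name = "copies")
  stats <- counts |>
    group_by(.data$cluster_id) |>
    summarise(
      n_present = n(),
      max_c = max(.data$copies),
      min_present = min(.data$copies),
      n_at_target = sum(.data$copies == target_count),
      .groups = "drop"
    ) |>
    mutate(
      # absent proteomes have copy count 0
      n_absent = n - .data$n_present,
      min_c = if_else(.data$n_absent > 0, 0L, .data$min_present),
      n_at_target = .data$n_at_target + if (target_count == 0L) .data$n_absent else 0L
    )
  ok <- stats |>
    filter(
      .data$min_c >= min_count,
      .data$max_c <= max_count,
      # exact rational comparison: n_at_target / n >= target_fraction
      .data$n_at_target >= ceiling_frac(target_fraction, n)
    )
  tibble(cluster_id = intersect(ids, ok$cluster_id))
}

# smallest integer k with k / n >= frac, robust to float representation
ceiling_frac <- function(frac, n) {
  k <- ceiling(frac * n - 1e-9)
  max(0, k)
}
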