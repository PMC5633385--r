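#' Pan-proteome rarefaction curves for the taxon sets of an attribute
#'
#' Borrowing the pangenome rarefaction framework from microbial genomics,
#' proteomes of each taxon set are sampled repeatedly in random order and the
#' cumulative number of distinct nonsingleton clusters recovered is recorded
#' after each addition. Singleton clusters (global size 1) are excluded
#' throughout. Curves are deterministic given `seed`.
#'
#' @param clustering A clustering tibble.
#' @param config A config tibble.
#' @param attribute Attribute whose levels are the sets to rarefy.
#' @param reps Number of random sampling repetitions (default 30).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A tibble with columns `attribute`, `level`, `rep`, `k` (number of
#'   proteomes sampled) and `n_clusters` (distinct nonsingleton clusters
#'   among the first `k` sampled proteomes).
#' @export
rarefaction_curve <- function(clustering, config, attribute, reps = 30, seed = NULL) {
  assert_clustering(clustering)
  if (reps < 1) abort("reps must be >= 1")
  sets <- taxon_sets(config, attribute)
  nonsingleton <- cluster_summary(clustering) |>
    filter(.data$size >= 2) |>
    pull("cluster_id")
  membership <- clustering |>
    filter(.data$cluster_id %in% nonsingleton) |>
    distinct(.data$proteome_id, .data$cluster_id)
  clusters_of <- split(membership$cluster_id, membership$proteome_id)

  with_seed(seed, {
    res <- lapply(unique(sets$level), function(lv) {
      prot <- sets$proteome_id[sets$level == lv]
      per_rep <- lapply(seq_len(reps), function(r) {
        perm <- sample(prot, length(prot))
        seen <- character(0)
        counts <- integer(length(prot))
        for (k in seq_along(perm)) {
          seen <- union(seen, clusters_of[[perm[k]]])
          counts[k] <- length(seen)
        }
        tibble(rep = r, k = seq_along(prot), n_clusters = counts)
      })
      bind_rows(per_rep) |> mutate(attribute = attribute, level = lv)
    })
    bind_rows(res) |> select("attribute", "level", "rep", "k", "n_clusters")
  })
}
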