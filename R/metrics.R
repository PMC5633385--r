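#' Per-cluster length and secretion metrics
#'
#' Computes mean and sample (n-1) standard deviation of member protein lengths
#' and the fraction of member proteins carrying at least one `SignalP_EUK`
#' signal-peptide annotation (putatively secreted). The SD of a singleton
#' cluster is undefined and reported as `NA`.
#'
#' @param clustering A clustering tibble.
#' @param lengths Optional tibble from [read_fasta_lengths()]. Proteins
#'   missing from it are excluded from length statistics with a warning.
#' @param annotations Optional annotation tibble from [read_interproscan()].
#' @param secretion_source Namespace marking secreted proteins
#'   (default `"SignalP_EUK"`; matched case-insensitively).
#' @return A tibble with `cluster_id`, `size`, `proteome_count`,
#'   `mean_length`, `sd_length`, `secreted_fraction` (all `NA` when the
#'   corresponding input is absent).
#' @export
cluster_metrics <- function(clustering, lengths = NULL, annotations = NULL,
                            secretion_source = "SignalP_EUK") {
  out <- cluster_summary(clustering)
  if (!is.null(lengths)) {
    missing <- setdiff(clustering$protein_id, lengths$protein_id)
    if (length(missing) > 0) {
      warn(sprintf("%d protein(s) have no length record; excluded from length stats",
                   length(missing)))
    }
    lstats <- clustering |>
      inner_join(lengths, by = "protein_id") |>
      group_by(.data$cluster_id) |>
      summarise(
        mean_length = mean(.data$length),
        sd_length = if_else(n() > 1, sd(.data$length), NA_real_),
        .groups = "drop"
      )
    out <- left_join(out, lstats, by = "cluster_id")
  } else {
    out$mean_length <- NA_real_
    out$sd_length <- NA_real_
  }
  if (!is.null(annotations)) {
    secreted <- annotations |>
      filter(tolower(.data$source) == tolower(secretion_source)) |>
      distinct(.data$protein_id) |>
      mutate(secreted = TRUE)
    frac <- clustering |>
      left_join(secreted, by = "protein_id") |>
      group_by(.data$cluster_id) |>
      summarise(secreted_fraction = mean(!is.na(.data$secreted)), .groups = "drop")
    out <- left_join(out, frac, by = "cluster_id")
  } else {
    out$secreted_fraction <- NA_real_
  }
  out
}

#' Shannon entropy of annotation terms within clusters
#'
#' For each cluster, terms of the given namespace are weighted by the number
#' of member proteins carrying them: with `c_d` proteins carrying term `d`,
#' `p_d = c_d / sum(c_d)` and `H = -sum(p_d * log2(p_d))` bits. Clusters with
#' no annotation in the namespace get `NA`.
#'
#' @param clustering A clustering tibble.
#' @param annotations Annotation tibble from [read_interproscan()].
#' @param namespace Annotation namespace (e.g. `"Pfam"`, `"GO"`, `"IPR"`).
#' @return A tibble with `cluster_id`, `namespace`, `entropy` (bits) covering
#'   every cluster of the clustering.
#' @export
annotation_entropy <- function(clustering, annotations, namespace) {
  assert_clustering(clustering)
  ids <- keep_cluster_order(clustering)
  ann <- annotations |> filter(.data$source == namespace)
  h <- clustering |>
    inner_join(ann, by = "protein_id", relationship = "many-to-many") |>
    distinct(.data$cluster_id, .data$protein_id, .data$term_id) |>
    count(.data$cluster_id, .data$term_id) |>
    group_by(.data$cluster_id) |>
    summarise(entropy = shannon_bits(.data$n), .groups = "drop")
  tibble(cluster_id = ids, namespace = namespace) |>
    left_join(h, by = "cluster_id")
}

shannon_bits <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}
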