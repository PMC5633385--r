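#' Plot a cluster size distribution with its reference power law
#'
#' Log-log frequency histogram of cluster sizes, colored by the number of
#' contributing proteomes, with per-size totals and the fitted power-law
#' reference curve overlaid (when available).
#'
#' @param distribution Output of [cluster_size_distribution()].
#' @param fit Optional [fit_power_law()] result; computed from
#'   `distribution` when `NULL`.
#' @return A ggplot object.
#' @export
plot_cluster_sizes <- function(distribution, fit = NULL) {
  fit <- fit %||% fit_power_law(distribution)
  totals <- distribution |>
    group_by(.data$size) |>
    summarise(n_clusters = sum(.data$n_clusters), .groups = "drop")
  p <- ggplot2::ggplot(distribution,
                       ggplot2::aes(.data$size, .data$n_clusters)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$proteome_count)),
                        alpha = 0.8) +
    ggplot2::geom_point(data = totals, colour = "grey40", shape = 1, size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Cluster size (proteins)", y = "Clusters",
                  colour = "Proteomes") +
    ggplot2::theme_minimal()
  if (isTRUE(fit$available)) {
    curve_df <- tibble(
      size = exp(seq(log(min(totals$size)), log(max(totals$size)), length.out = 100))
    )
    curve_df$n_clusters <- fit$C * curve_df$size^(-fit$gamma)
    p <- p + ggplot2::geom_line(data = curve_df, colour = "grey60")
  }
  p
}

#' Plot rarefaction curves
#'
#' Median and per-repetition spread of the cumulative nonsingleton-cluster
#' counts from [rarefaction_curve()], one curve per taxon set.
#'
#' @param curve Output of [rarefaction_curve()].
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curve) {
  summ <- curve |>
    group_by(.data$level, .data$k) |>
    summarise(
      median = stats::median(.data$n_clusters),
      lo = min(.data$n_clusters), hi = max(.data$n_clusters),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(.data$k, .data$median, colour = .data$level,
                                     fill = .data$level)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Proteomes sampled", y = "Nonsingleton clusters",
                  colour = "Taxon set", fill = "Taxon set") +
    ggplot2::theme_minimal()
}

#' Volcano plot of representation-test results
#'
#' `log2` fold change of mean counts against the test p-value, with guide
#' lines at p = 0.05 and 0.01 (horizontal) and at `|log2fc| = 1` and the
#' 95th percentile of `|log2fc|` (vertical).
#'
#' @param results Output of [representation_test()] or [volcano_table()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(results) {
  p95 <- attr(results, "p95_abs_log2fc") %||%
    unname(quantile(abs(results$log2fc), 0.95, type = 7, na.rm = TRUE))
  df <- dplyr::mutate(tibble::as_tibble(results), neglog10p = -log10(.data$pvalue))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neglog10p)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(c(0.05, 0.01)), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-p95, p95), linetype = "dotted",
                        colour = "grey30") +
    ggplot2::labs(x = "log2 fold change of mean counts",
                  y = expression(-log[10] ~ italic(P))) +
    ggplot2::theme_minimal()
}
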