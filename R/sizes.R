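#' Cluster size distribution with proteome-count breakdown
#'
#' Frequency histogram of cluster size (number of member proteins), broken
#' down by the number of proteomes contributing to each cluster. Deviations
#' from the expected power-law-like decay — e.g. a local excess at a size
#' equal to the number of input proteomes, where single-copy orthologs
#' accumulate — are diagnostic features of a clustering.
#'
#' @param clustering A clustering tibble.
#' @return A tibble with columns `size`, `proteome_count`, `n_clusters`.
#' @export
cluster_size_distribution <- function(clustering) {
  cluster_summary(clustering) |>
    count(.data$size, .data$proteome_count, name = "n_clusters") |>
    arrange(.data$size, .data$proteome_count)
}

#' Fit a reference power law to a cluster size distribution
#'
#' Fits `n_clusters = C * size^(-gamma)` by ordinary least squares on the
#' log-log histogram (zero-count bins excluded). The fit is descriptive — a
#' reference curve for plots — not an inferential power-law test.
#'
#' @param distribution Output of [cluster_size_distribution()] (the
#'   proteome-count breakdown, if present, is collapsed), or any tibble with
#'   columns `size` and `n_clusters`.
#' @return An object of class `powerlaw_fit` with elements `C`, `gamma`,
#'   `fit` (the underlying `lm`), `data`, and `available` (`FALSE` when fewer
#'   than two distinct sizes were observed, in which case no fit is made).
#' @export
fit_power_law <- function(distribution) {
  if (!all(c("size", "n_clusters") %in% names(distribution))) {
    abort("`distribution` needs columns size and n_clusters")
  }
  totals <- distribution |>
    group_by(.data$size) |>
    summarise(n_clusters = sum(.data$n_clusters), .groups = "drop") |>
    filter(.data$n_clusters > 0)
  if (nrow(totals) < 2) {
    return(structure(
      list(C = NA_real_, gamma = NA_real_, fit = NULL, data = totals, available = FALSE),
      class = "powerlaw_fit"
    ))
  }
  fit <- lm(log(n_clusters) ~ log(size), data = totals)
  structure(
    list(
      C = unname(exp(coef(fit)[1])),
      gamma = unname(-coef(fit)[2]),
      fit = fit,
      data = totals,
      available = TRUE
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (!x$available) {
    cat("Power-law fit unavailable (fewer than two distinct cluster sizes)\n")
  } else {
    cat(sprintf("Power-law fit: n = %.4g * size^(-%.4g)  [%d size bins]\n",
                x$C, x$gamma, nrow(x$data)))
  }
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x A `powerlaw_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`C`, `gamma`).
#' @export
#' @method tidy powerlaw_fit
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("C", "gamma"), estimate = c(x$C, x$gamma))
}

#' One-row summary of a power-law fit
#'
#' @param x A `powerlaw_fit` object.
#' @param ... Unused.
#' @return A tibble with `C`, `gamma`, `r.squared`, `n_bins`, `available`.
#' @export
#' @method glance powerlaw_fit
glance.powerlaw_fit <- function(x, ...) {
  tibble(
    C = x$C, gamma = x$gamma,
    r.squared = if (x$available) {
      # collinear log-log points trigger a "perfect fit" note from summary.lm
      suppressWarnings(summary(x$fit)$r.squared)
    } else NA_real_,
    n_bins = nrow(x$data),
    available = x$available
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
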