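#' Two-sided p-value for a protein-count comparison
#'
#' The workhorse behind [representation_test()]. For the Mann-Whitney U test,
#' an exact two-sided p-value is computed by full enumeration of all
#' assignments of the pooled counts to the two groups whenever
#' `min(n1, n2) <= 8` (ties handled through midranks); larger samples use the
#' normal approximation with tie and continuity correction. `welch` and
#' `student` are two-sample t-tests with unequal and pooled variance.
#'
#' @param x,y Numeric vectors of per-proteome protein counts.
#' @param method One of `"mwu"`, `"welch"`, `"student"`.
#' @return A single p-value in `[0, 1]`; 1.0 when all counts are identical
#'   across both groups; `NA` when the test statistic is undefined.
#' @examples
#' count_test_pvalue(c(1, 1, 2), c(5, 6, 7)) # exact, 0.1
#' @export
count_test_pvalue <- function(x, y, method = c("mwu", "welch", "student")) {
  method <- match.arg(method)
  if (length(unique(c(x, y))) == 1) {
    return(1.0)
  }
  if (method == "mwu") {
    if (min(length(x), length(y)) <= 8) {
      return(mwu_exact_p(x, y))
    }
    return(suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    ))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    # constant but unequal groups: t statistic undefined
    return(NA_real_)
  }
  tryCatch(
    t.test(x, y, var.equal = (method == "student"))$p.value,
    error = function(e) NA_real_
  )
}

# exact two-sided MWU p-value by enumeration of all C(n, n1) group
# assignments of the pooled sample; extremeness measured as |U - n1*n2/2|
mwu_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  idx <- combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Pairwise protein-count representation tests between two taxon sets
#'
#' For every cluster containing at least one protein from each of two taxon
#' sets, compares the per-proteome protein counts between the sets. Count
#' vectors cover all proteomes of each set, including zeros for set members
#' absent from the cluster — absence carries the depletion signal. P-values
#' are reported raw (no multiple-testing correction); guide thresholds are
#' drawn on the volcano plot instead.
#'
#' @param clustering A clustering tibble.
#' @param config A config tibble.
#' @param attribute Attribute containing the two levels.
#' @param level_a,level_b Level names to compare.
#' @param method Test: `"mwu"` (default), `"welch"` or `"student"`.
#' @return A tibble with one row per tested cluster: `cluster_id`, `level_a`,
#'   `level_b`, list columns `counts_a`/`counts_b`, `mean_a`, `mean_b`,
#'   `log2fc` (`log2(mean_a / mean_b)`), `pvalue` and `method`. `pvalue` is
#'   `NA` when either set has fewer than two proteomes.
#' @export
representation_test <- function(clustering, config, attribute, level_a, level_b,
                                method = c("mwu", "welch", "student")) {
  method <- match.arg(method)
  assert_clustering(clustering)
  sets <- taxon_sets(config, attribute)
  prot_a <- sets$proteome_id[sets$level == level_a]
  prot_b <- sets$proteome_id[sets$level == level_b]
  if (length(prot_a) == 0 || length(prot_b) == 0) {
    abort(sprintf("level '%s' or '%s' not found under attribute '%s'",
                  level_a, level_b, attribute))
  }
  counts <- clustering |>
    count(.data$cluster_id, .data$proteome_id, name = "copies")
  # clusters with >=1 protein from each set
  in_a <- unique(counts$cluster_id[counts$proteome_id %in% prot_a])
  in_b <- unique(counts$cluster_id[counts$proteome_id %in% prot_b])
  test_ids <- intersect(keep_cluster_order(clustering), intersect(in_a, in_b))
  testable <- length(prot_a) >= 2 && length(prot_b) >= 2

  by_cluster <- split(counts[c("proteome_id", "copies")], counts$cluster_id)
  rows <- lapply(test_ids, function(cid) {
    cc <- by_cluster[[cid]]
    va <- cc$copies[match(prot_a, cc$proteome_id)]
    va[is.na(va)] <- 0
    vb <- cc$copies[match(prot_b, cc$proteome_id)]
    vb[is.na(vb)] <- 0
    tibble(
      cluster_id = cid,
      level_a = level_a, level_b = level_b,
      counts_a = list(va), counts_b = list(vb),
      mean_a = mean(va), mean_b = mean(vb),
      log2fc = log2(mean(va) / mean(vb)),
      pvalue = if (testable) count_test_pvalue(va, vb, method) else NA_real_,
      method = method
    )
  })
  bind_rows(rows)
}

#' Volcano table of representation-test results
#'
#' Orders results by ascending p-value and records the 95th percentile of
#' `|log2fc|` (linear interpolation), the quantity marked by the outer
#' vertical guide lines of [plot_volcano()].
#'
#' @param results Output of [representation_test()].
#' @return The results tibble sorted by p-value, with attribute
#'   `p95_abs_log2fc`.
#' @export
volcano_table <- function(results) {
  if (nrow(results) == 0) abort("no representation-test results to tabulate")
  out <- arrange(results, .data$pvalue)
  attr(out, "p95_abs_log2fc") <-
    unname(quantile(abs(results$log2fc), 0.95, type = 7, na.rm = TRUE))
  out
}
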