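toy <- toy3_fixture()

test_that("rarefaction curves end at the set's nonsingleton cluster count and are seed-deterministic", {
  curve <- rarefaction_curve(toy$clustering, toy$config, "all", reps = 10, seed = 7)
  ends <- curve[curve$k == 3, ]
  expect_true(all(ends$n_clusters == 4)) # OG0, OG1, OG2, OG4

  curve2 <- rarefaction_curve(toy$clustering, toy$config, "all", reps = 10, seed = 7)
  expect_identical(curve, curve2)
  curve3 <- rarefaction_curve(toy$clustering, toy$config, "all", reps = 10, seed = 8)
  expect_false(identical(curve, curve3))

  # counts nondecreasing within a repetition
  b <- generate_bundle(fixture_spec(), seed = 13)
  cb <- rarefaction_curve(b$clustering, b$config, "clade", reps = 5, seed = 1)
  deltas <- cb |>
    dplyr::group_by(level, rep) |>
    dplyr::summarise(ok = all(diff(n_clusters) >= 0), .groups = "drop")
  expect_true(all(deltas$ok))
  # endpoint identity on every repetition
  nonsing <- cluster_summary(b$clustering) |> dplyr::filter(size >= 2)
  for (lv in unique(b$config$clade)) {
    prot <- b$config$proteome_id[b$config$clade == lv]
    expected <- b$clustering |>
      dplyr::filter(cluster_id %in% nonsing$cluster_id, proteome_id %in% prot) |>
      dplyr::pull(cluster_id) |>
      dplyr::n_distinct()
    ends <- cb[cb$level == lv & cb$k == length(prot), ]
    expect_true(all(ends$n_clusters == expected))
  }
})

test_that("a single-proteome set yields a one-point curve", {
  curve <- rarefaction_curve(toy$clustering, toy$config, "TAXON", reps = 3, seed = 1)
  cA <- curve[curve$level == "A", ]
  expect_equal(unique(cA$k), 1)
  expect_true(all(cA$n_clusters == 4)) # A's nonsingleton clusters
})

test_that("MWU p-values match exact enumeration and behave under swap and degeneracy", {
  expect_equal(count_test_pvalue(c(1, 1, 2), c(5, 6, 7), "mwu"), 0.1)
  expect_equal(count_test_pvalue(c(5, 6, 7), c(1, 1, 2), "mwu"), 0.1) # symmetry
  expect_equal(count_test_pvalue(c(2, 2), c(2, 2), "mwu"), 1.0)
  expect_equal(count_test_pvalue(c(2, 2), c(2, 2), "welch"), 1.0)
  # approximation tracks exact enumeration on tie-free n=8 samples
  withr::local_seed(23)
  for (i in 1:50) {
    v <- sample(1:100, 16)
    ex <- clusterkin:::mwu_exact_p(v[1:8], v[9:16])
    ap <- suppressWarnings(wilcox.test(v[1:8], v[9:16], exact = FALSE,
                                       correct = TRUE)$p.value)
    expect_lt(abs(ex - ap), 0.02)
  }
})

test_that("representation tests use zero-filled count vectors and closed-form log2fc", {
  cl <- dplyr::bind_rows(
    profile_clustering(c("A", "B", "C", "D", "E", "F"),
                       c(A = 1L, B = 1L, C = 2L, D = 5L, E = 6L, F = 7L))
  )
  cfg <- tibble::tibble(proteome_id = c("A", "B", "C", "D", "E", "F"),
                        side = rep(c("left", "right"), each = 3))
  cfg$all <- "all"; cfg$TAXON <- cfg$proteome_id
  rt <- representation_test(cl, cfg, "side", "left", "right")
  expect_equal(rt$log2fc, log2((4 / 3) / 6), tolerance = 1e-6)
  expect_equal(rt$pvalue, 0.1)
  rt_swap <- representation_test(cl, cfg, "side", "right", "left")
  expect_equal(rt_swap$log2fc, -rt$log2fc)
  expect_equal(rt_swap$pvalue, rt$pvalue)

  # zero counts included: cluster absent from one left proteome
  cl2 <- profile_clustering(c("A", "B", "D", "E", "F"),
                            c(A = 1L, B = 1L, D = 2L, E = 2L, F = 2L))
  rt2 <- representation_test(cl2, cfg, "side", "left", "right")
  expect_equal(rt2$counts_a[[1]], c(1, 1, 0))
  expect_equal(rt2$mean_a, 2 / 3)

  # clusters lacking one side entirely are skipped
  cl3 <- profile_clustering(c("A", "B"), c(A = 1L, B = 1L))
  expect_equal(nrow(representation_test(cl3, cfg, "side", "left", "right")), 0)

  # p-value NA when a set has fewer than two proteomes
  cfg_small <- tibble::tibble(proteome_id = c("A", "B", "C"),
                              host = c("human", "human", "other"))
  cfg_small$all <- "all"; cfg_small$TAXON <- cfg_small$proteome_id
  rt4 <- representation_test(toy$clustering, cfg_small, "host", "human", "other")
  expect_true(all(is.na(rt4$pvalue)))
})

test_that("volcano tables sort by p-value and record the 95th percentile", {
  res <- tibble::tibble(
    cluster_id = c("c1", "c2", "c3"),
    log2fc = c(0.5, -2, 1),
    pvalue = c(0.2, 0.04, 0.005)
  )
  vt <- volcano_table(res)
  expect_equal(vt$pvalue, c(0.005, 0.04, 0.2))

  same <- tibble::tibble(cluster_id = "x", log2fc = 1.25, pvalue = 0.5)
  expect_equal(attr(volcano_table(same), "p95_abs_log2fc"), 1.25)

  hundred <- tibble::tibble(
    cluster_id = sprintf("c%d", 1:100),
    log2fc = seq(0.02, 2, by = 0.02) * rep(c(1, -1), 50),
    pvalue = runif(100)
  )
  p95 <- attr(volcano_table(hundred), "p95_abs_log2fc")
  expect_equal(p95, unname(quantile(seq(0.02, 2, by = 0.02), 0.95, type = 7)))
  expect_equal(p95, 1.9, tolerance = 0.01)
})

test_that("size histograms tally correctly and the power-law fit recovers gamma exactly", {
  dist <- cluster_size_distribution(toy$clustering)
  totals <- dist |> dplyr::group_by(size) |> dplyr::summarise(n = sum(n_clusters))
  expect_equal(totals$n, c(2, 2, 2)) # sizes 1, 2, 3

  exact <- tibble::tibble(size = c(1, 2, 4), n_clusters = c(16, 4, 1))
  fit <- fit_power_law(exact)
  expect_equal(fit$gamma, 2.0, tolerance = 1e-10)
  expect_equal(fit$C, 16, tolerance = 1e-8)
  expect_equal(tidy(fit)$estimate, c(16, 2), tolerance = 1e-8)
  expect_true(glance(fit)$available)

  degenerate <- tibble::tibble(size = 2, n_clusters = 10)
  expect_false(fit_power_law(degenerate)$available)
})

test_that("co-occurrence weights count shared clusters and respect the universal filter", {
  edges <- cooccurrence_edges(toy$clustering)
  w <- function(e, u, v) e$weight[e$from == u & e$to == v]
  expect_equal(w(edges, "A", "B"), 3) # OG0, OG1, OG4
  edges_nu <- cooccurrence_edges(toy$clustering, exclude_universal = TRUE)
  expect_equal(w(edges_nu, "A", "B"), 1) # OG1 only
  expect_false(any(edges_nu$to == "C" | edges_nu$from == "C"))

  # symmetry is structural (from < to); weight bounded by per-proteome cluster counts
  b <- generate_bundle(fixture_spec(), seed = 3)
  eb <- cooccurrence_edges(b$clustering)
  per_prot <- b$clustering |>
    dplyr::distinct(cluster_id, proteome_id) |>
    dplyr::count(proteome_id)
  lim <- stats::setNames(per_prot$n, per_prot$proteome_id)
  expect_true(all(eb$weight <= pmin(lim[eb$from], lim[eb$to])))

  tf <- withr::local_tempfile(fileext = ".graphml")
  write_cooccurrence_graphml(edges, tf, proteomes = c("A", "B", "C"))
  g <- igraph::read_graph(tf, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), nrow(edges))
})
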