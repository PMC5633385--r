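toy <- toy3_fixture()

test_that("cluster typing follows the singleton/specific/shared rule", {
  types_taxon <- classify_clusters(toy$clustering, toy$config, "TAXON")
  expect_equal(types_taxon$cluster_type[types_taxon$cluster_id == "OG2"], "specific")
  expect_equal(types_taxon$cluster_type[types_taxon$cluster_id == "OG3"], "singleton")

  types_host <- classify_clusters(toy$clustering, toy$config, "host")
  # {a2, b2}: two proteomes but one host level -> specific under host, shared under TAXON
  expect_equal(types_host$cluster_type[types_host$cluster_id == "OG1"], "specific")
  expect_equal(types_taxon$cluster_type[types_taxon$cluster_id == "OG1"], "shared")
  # singletons are singletons under every attribute
  for (a in config_attributes(toy$config)) {
    tt <- classify_clusters(toy$clustering, toy$config, a)
    expect_equal(tt$cluster_type[tt$cluster_id == "OG5"], "singleton")
  }
})

test_that("every cluster gets exactly one type and proteins are conserved across types", {
  b <- generate_bundle(fixture_spec(), seed = 5)
  for (a in config_attributes(b$config)) {
    types <- classify_clusters(b$clustering, b$config, a)
    expect_equal(nrow(types), dplyr::n_distinct(b$clustering$cluster_id))
    expect_true(all(types$cluster_type %in% c("singleton", "specific", "shared")))
    by_type <- dplyr::left_join(b$clustering, types, by = "cluster_id") |>
      dplyr::count(cluster_type)
    expect_equal(sum(by_type$n), nrow(b$clustering)) # Fig-2-style stacking
  }
  # under TAXON, a single-proteome cluster is never "shared"
  types <- classify_clusters(b$clustering, b$config, "TAXON")
  single_prot <- cluster_summary(b$clustering) |> dplyr::filter(proteome_count == 1)
  expect_false(any(types$cluster_type[types$cluster_id %in% single_prot$cluster_id] == "shared"))
})

test_that("count and presence matrices tally membership per level", {
  counts <- cluster_level_counts(toy$clustering, toy$config, "TAXON")
  expect_equal(colSums(counts[, -1]), c(A = 5, B = 4, C = 3)) # per-level protein totals
  pres <- cluster_level_presence(toy$clustering, toy$config, "TAXON")
  expect_equal(rowSums(pres[, -1]),
               c(3, 2, 1, 1, 3, 1)[match(pres$cluster_id, paste0("OG", 0:5))])
  # single-level partition: every multi-protein cluster specific to "all"
  types_all <- classify_clusters(toy$clustering, toy$config, "all")
  expect_true(all(types_all$cluster_type[types_all$n_levels == 1 &
                                           types_all$cluster_type != "singleton"] == "specific"))
})

test_that("level summaries partition clusters and proteins", {
  summ <- level_summary(toy$clustering, toy$config, "host")
  expect_equal(summ$clusters_total,
               summ$clusters_singleton + summ$clusters_specific + summ$clusters_shared)
  expect_equal(sum(summ$proteins_total), nrow(toy$clustering))
  human <- summ[summ$level == "human", ]
  expect_equal(human$n_proteomes, 2)
  expect_equal(human$proteins_total, 9) # A(5) + B(4)
})

test_that("length and secretion metrics match closed forms", {
  cl <- tibble::tibble(cluster_id = "c1", proteome_id = c("A", "B"),
                       protein_id = c("p1", "p2"))
  lens <- tibble::tibble(protein_id = c("p1", "p2"), length = c(100L, 200L))
  m <- cluster_metrics(cl, lens)
  expect_equal(m$mean_length, 150.0)
  expect_equal(m$sd_length, 70.710678, tolerance = 1e-6)

  toy_m <- cluster_metrics(toy$clustering, toy$lengths, toy$annotations)
  # singleton SD undefined
  expect_true(all(is.na(toy_m$sd_length[toy_m$size == 1])))
  # OG4 has 2 of 3 members SignalP_EUK-flagged; OG0 none
  expect_equal(toy_m$secreted_fraction[toy_m$cluster_id == "OG4"], 2 / 3)
  expect_equal(toy_m$secreted_fraction[toy_m$cluster_id == "OG0"], 0.0)
})

test_that("metrics warn on missing lengths and exclude those proteins", {
  cl <- tibble::tibble(cluster_id = "c1", proteome_id = c("A", "B"),
                       protein_id = c("p1", "p2"))
  lens <- tibble::tibble(protein_id = "p1", length = 100L)
  expect_warning(m <- cluster_metrics(cl, lens), "no length")
  expect_equal(m$mean_length, 100)
})

test_that("annotation entropy follows the incidence-weighted Shannon formula", {
  mk_ann <- function(protein_id, term_id) {
    tibble::tibble(protein_id = protein_id, source = "Pfam",
                   term_id = term_id, description = "")
  }
  cl4 <- tibble::tibble(cluster_id = "c1", proteome_id = "A",
                        protein_id = paste0("p", 1:4))
  # one term on all proteins -> 0 bits
  e0 <- annotation_entropy(cl4, mk_ann(paste0("p", 1:4), "d1"), "Pfam")
  expect_equal(e0$entropy, 0.0)
  # two terms, each on 2 of 4 -> 1 bit
  e1 <- annotation_entropy(cl4, mk_ann(paste0("p", 1:4), c("d1", "d1", "d2", "d2")), "Pfam")
  expect_equal(e1$entropy, 1.0)
  # three terms with protein counts 2,1,1 -> 1.5 bits
  e15 <- annotation_entropy(cl4, mk_ann(paste0("p", 1:4), c("d1", "d1", "d2", "d3")), "Pfam")
  expect_equal(e15$entropy, 1.5)
  # no annotation in namespace -> NA
  eNA <- annotation_entropy(cl4, mk_ann("p1", "d1"), "GO")
  expect_true(is.na(eNA$entropy))
})
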