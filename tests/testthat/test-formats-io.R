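test_that("sequence ID files parse, resolve proteome indices, and reject malformed lines", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines("0_0: A_prot1", tf)
  sm <- read_sequence_ids(tf, c("A", "B"))
  expect_equal(sm$token, "0_0")
  expect_equal(sm$protein_id, "A_prot1")
  expect_equal(sm$proteome_id, "A")

  toy <- toy3_fixture(dir = withr::local_tempdir())
  sm3 <- read_sequence_ids(toy$paths$seqids, toy$config$proteome_id)
  expect_equal(nrow(sm3), 12)
  expect_equal(dplyr::n_distinct(sm3$proteome_id), 3)

  writeLines("0_0 A_prot1", tf)
  expect_error(read_sequence_ids(tf, "A"), "line 1")
  writeLines(c("0_0: p1", "0_0: p2"), tf)
  expect_error(read_sequence_ids(tf, "A"), "duplicate")
})

test_that("cluster files parse through the sequence map and report bad tokens", {
  tf <- withr::local_tempfile(fileext = ".txt")
  sm <- tibble::tibble(token = c("0_0", "1_0"), protein_id = c("a1", "b1"),
                       proteome_id = c("A", "B"))
  writeLines("OG0: 0_0 1_0", tf)
  cl <- read_clustering(tf, sm)
  expect_equal(nrow(cl), 2)
  cs <- cluster_summary(cl)
  expect_equal(cs$size, 2)
  expect_equal(cs$proteome_count, 2)

  writeLines("OG0: 0_0 9_9", tf)
  expect_error(read_clustering(tf, sm), "9_9")
  writeLines("OG0:", tf)
  expect_error(read_clustering(tf, sm), "no members")

  toy <- toy3_fixture(dir = withr::local_tempdir())
  cl6 <- read_clustering(toy$paths$clustering,
                         read_sequence_ids(toy$paths$seqids, toy$config$proteome_id))
  expect_equal(dplyr::n_distinct(cl6$cluster_id), 6)
  expect_equal(nrow(cl6), 12) # total members = sum of token counts
})

test_that("raw-protein-ID cluster files are auto-detected", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("OG0: a1 b1", "OG1: a2"), tf)
  sm <- tibble::tibble(token = c("0_0", "0_1", "1_0"),
                       protein_id = c("a1", "a2", "b1"),
                       proteome_id = c("A", "A", "B"))
  cl <- read_clustering(tf, sm)
  expect_equal(sort(cl$protein_id), c("a1", "a2", "b1"))
  expect_equal(cl$proteome_id[cl$protein_id == "b1"], "B")
})

test_that("clustering round-trips through the cluster-file format", {
  toy <- toy3_fixture()
  tf <- withr::local_tempfile(fileext = ".txt")
  write_clustering(toy$clustering, tf)
  back <- read_clustering(tf, protein_proteomes = toy$seqmap[, c("protein_id", "proteome_id")])
  expect_identical(back, toy$clustering)
})

test_that("permuting cluster-file lines changes row order but no statistic", {
  toy <- toy3_fixture(dir = withr::local_tempdir())
  lines <- readLines(toy$paths$clustering)
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(rev(lines), tf)
  sm <- read_sequence_ids(toy$paths$seqids, toy$config$proteome_id)
  perm <- read_clustering(tf, sm)
  orig <- toy$clustering
  expect_identical(dplyr::arrange(perm, cluster_id, protein_id),
                   dplyr::arrange(orig, cluster_id, protein_id))
  expect_identical(
    dplyr::arrange(cluster_summary(perm), cluster_id),
    dplyr::arrange(cluster_summary(orig), cluster_id)
  )
  expect_setequal(find_true_scos(perm)$cluster_id, find_true_scos(orig)$cluster_id)
})

test_that("config tables gain the reserved 'all' and 'TAXON' attributes", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#IDX,TAXON,host", "0,A,human", "1,B,human", "2,C,other"), tf)
  cfg <- read_attribute_config(tf)
  expect_setequal(config_attributes(cfg), c("host", "all", "TAXON"))
  sets <- taxon_sets(cfg, "host")
  expect_setequal(sets$proteome_id[sets$level == "human"], c("A", "B"))
  expect_equal(sets$proteome_id[sets$level == "other"], "C")
  expect_equal(dplyr::n_distinct(taxon_sets(cfg, "all")$level), 1)
  expect_equal(dplyr::n_distinct(taxon_sets(cfg, "TAXON")$level), 3)

  writeLines(c("#IDX,TAXON,host", "0,A,human", "1,A,other"), tf)
  expect_error(read_attribute_config(tf), "duplicate")
  writeLines(c("#IDX,TAXON,host", "0,A"), tf)
  expect_error(read_attribute_config(tf), "fields")
})

test_that("InterProScan rows expand into namespaces and collapse duplicates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  row <- paste("p1", "md5", "300", "Pfam", "PF00001", "A domain", "1", "100",
               "1e-10", "T", "01-01-2020", "IPR000001", "A family",
               "GO:0005524|GO:0016021", sep = "\t")
  writeLines(row, tf)
  ann <- read_interproscan(tf)
  expect_equal(nrow(ann), 4)
  expect_setequal(ann$source, c("Pfam", "IPR", "GO"))
  expect_equal(sum(ann$source == "GO"), 2)

  writeLines(c(row, row), tf) # second domain hit of the same signature
  ann2 <- read_interproscan(tf)
  expect_identical(ann2, ann)

  writeLines("p1\tonly-two-cols", tf)
  expect_error(read_interproscan(tf), "line 1")
})

test_that("annotation tables cover exactly the annotated proteins of a fixture", {
  b <- generate_bundle(fixture_spec(), dir = withr::local_tempdir(), seed = 11)
  ann <- read_interproscan(b$paths$annotations)
  raw <- readLines(b$paths$annotations)
  expected <- length(unique(vapply(strsplit(raw, "\t"), `[`, character(1), 1)))
  expect_equal(dplyr::n_distinct(ann$protein_id), expected)
  expect_lt(expected, dplyr::n_distinct(b$clustering$protein_id))
})

test_that("FASTA lengths strip terminal stops and reject duplicates", {
  tf <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 desc", "MKV"), tf)
  expect_equal(read_fasta_lengths(tf)$length, 3)
  writeLines(c(">p1", "MKV*"), tf)
  expect_equal(read_fasta_lengths(tf)$length, 3)
  tf2 <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MAAA"), tf2)
  expect_error(read_fasta_lengths(c(tf, tf2)), "duplicate")

  toy <- toy3_fixture(dir = withr::local_tempdir())
  lens <- read_fasta_lengths(toy$paths$fasta)
  expect_identical(
    dplyr::arrange(lens, protein_id),
    dplyr::arrange(toy$lengths, protein_id)
  )
})

test_that("trees root on the outgroup and label internal nodes in preorder", {
  tr <- read_tree_topology("((A,B),C);", outgroups = "C")
  lu <- leaves_under(tr)
  expect_setequal(lu$n0, c("A", "B", "C"))
  expect_setequal(lu$n1, c("A", "B"))

  tr2 <- read_tree_topology("((A,B),(C,D));")
  expect_setequal(leaves_under(tr2)$n0, c("A", "B", "C", "D"))

  tr3 <- read_tree_topology("((A,(B,C)),D);", outgroups = "D")
  lu3 <- leaves_under(tr3)
  expect_setequal(lu3$n1, c("A", "B", "C"))
  expect_setequal(lu3$n2, c("B", "C"))

  expect_error(read_tree_topology("((A,B),C);", outgroups = "Z"), "outgroup")
  expect_error(read_tree_topology("((A,B),C);", proteomes = c("A", "B")), "config")
})

test_that("taxonomy ranks resolve through a mini taxdump", {
  dir <- withr::local_tempdir()
  writeLines(c("1\t|\t1\t|\tno rank\t|", "10\t|\t1\t|\tphylum\t|",
               "20\t|\t10\t|\tgenus\t|", "100\t|\t20\t|\tspecies\t|",
               "101\t|\t10\t|\tspecies\t|"),
             file.path(dir, "nodes.dmp"))
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "10\t|\tNematoda\t|\t\t|\tscientific name\t|",
               "20\t|\tCaeno\t|\t\t|\tscientific name\t|",
               "100\t|\tSpecies one\t|\t\t|\tscientific name\t|",
               "101\t|\tSpecies two\t|\t\t|\tscientific name\t|"),
             file.path(dir, "names.dmp"))
  cfg <- tibble::tibble(proteome_id = c("A", "B", "C"),
                        TAXID = c("100", "101", "999"))
  cfg$all <- "all"; cfg$TAXON <- cfg$proteome_id
  expect_warning(
    cfg2 <- expand_taxonomy_ranks(cfg, file.path(dir, "nodes.dmp"),
                                  file.path(dir, "names.dmp"),
                                  ranks = c("phylum", "genus")),
    "999"
  )
  expect_equal(cfg2$phylum, c("Nematoda", "Nematoda", "undef"))
  expect_equal(cfg2$genus, c("Caeno", "undef", "undef")) # lineage of 101 lacks genus
  expect_true(all(c("phylum", "genus") %in% config_attributes(cfg2)))
})
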