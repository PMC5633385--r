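#' Specification for a synthetic input bundle
#'
#' Describes a deterministic, internally consistent synthetic orthology
#' dataset: a clustering, sequence IDs, attribute config, per-proteome
#' FASTAs, InterProScan-style annotation, a tree topology and a mini NCBI
#' taxdump, together with a ground-truth manifest derived at generation time
#' by direct rule application (independent of the analysis code paths).
#' Defaults are a scaled-down emulation of a multi-species clustering: a
#' handful of strict single-copy orthologs, fuzzy single-copy clusters with
#' a minority of duplicated proteomes, per-node synapomorphic clusters,
#' proteome-private (apomorphic) clusters, random shared clusters, and
#' protein lengths drawn from a normal distribution typical of proteomes
#' (mean 300 aa, SD 100 aa).
#'
#' @param n_proteomes Number of proteomes (leaves of the tree).
#' @param n_true_scos Strict single-copy ortholog clusters.
#' @param n_fuzzy_extra Clusters that are fuzzy but not strict SCOs (all
#'   proteomes present, a minority with two copies).
#' @param synapomorphies_per_node Complete-presence synapomorphic clusters
#'   implanted at every non-root internal node.
#' @param n_specific_per_proteome Nonsingleton proteome-private clusters per
#'   proteome.
#' @param n_singletons_per_proteome Singleton clusters per proteome.
#' @param n_shared_random Random shared clusters (random proteome subsets,
#'   copy counts 1-3).
#' @param ipr_fraction Fraction of nonsingleton clusters receiving a
#'   dedicated, fully covering Pfam+IPR+GO implant (ground-truth
#'   representative annotation).
#' @param secreted_fraction Fraction of proteins flagged `SignalP_EUK`.
#' @param length_mean,length_sd Protein length distribution (aa, truncated at
#'   50).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteomes = 8, n_true_scos = 8, n_fuzzy_extra = 4,
                         synapomorphies_per_node = 2,
                         n_specific_per_proteome = 2,
                         n_singletons_per_proteome = 4,
                         n_shared_random = 20,
                         ipr_fraction = 0.3, secreted_fraction = 0.15,
                         length_mean = 300, length_sd = 100) {
  spec <- as.list(environment())
  if (any(unlist(spec[c("n_proteomes", "n_true_scos", "n_fuzzy_extra",
                        "synapomorphies_per_node", "n_specific_per_proteome",
                        "n_singletons_per_proteome", "n_shared_random")]) < 0) ||
      n_proteomes < 3) {
    abort("fixture spec counts must be >= 0 and n_proteomes >= 3")
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic input bundle with ground truth
#'
#' Writes every input format consumed by the readers — `Orthogroups.txt`
#' (internal tokens), `SequenceIDs.txt`, `config.csv` (with a binary `clade`
#' attribute from the root split and a `TAXID` column), one FASTA per
#' proteome under `fasta/`, `annotations.tsv` (InterProScan dialect),
#' `tree.nwk`, and `taxdump/nodes.dmp` + `names.dmp` — and returns the
#' in-memory tables plus a manifest of expected analysis results computed by
#' direct application of the defining rules to the generated memberships.
#' Output is byte-identical for identical `(spec, seed)`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed); `NULL` skips file output.
#' @param seed Integer seed.
#' @return Invisibly, a list with `clustering`, `seqmap`, `config`,
#'   `lengths`, `annotations`, `tree_newick`, `dir`, `paths`, and `manifest`.
#' @export
generate_bundle <- function(spec = fixture_spec(), dir = NULL, seed = 1) {
  with_seed(seed, generate_bundle_impl(spec, dir))
}

generate_bundle_impl <- function(spec, dir) {
  n <- spec$n_proteomes
  proteomes <- sprintf("P%02d", seq_len(n))

  ## -- tree: random binary topology; preorder node records kept by hand
  nodes <- list() # each: list(label, leaves, left, right)
  counter <- new.env()
  counter$k <- 0L
  grow <- function(leaves) {
    if (length(leaves) == 1) return(leaves)
    lab <- sprintf("n%d", counter$k)
    counter$k <- counter$k + 1L
    cut <- if (length(leaves) == 2) 1L else sample(seq_len(length(leaves) - 1), 1)
    left <- leaves[seq_len(cut)]
    right <- leaves[-seq_len(cut)]
    nodes[[lab]] <<- list(label = lab, leaves = leaves, left = left, right = right)
    sprintf("(%s,%s)", grow(left), grow(right))
  }
  newick <- paste0(grow(sample(proteomes, n)), ";")

  ## -- clusters: build a member list (proteome -> copies) per cluster
  members <- list()   # cluster_id -> named integer vector of copies
  truth <- list(true_scos = character(0), fuzzy_scos = character(0))
  next_id <- new.env()
  next_id$k <- 0L
  add_cluster <- function(copies) {
    id <- sprintf("OG%06d", next_id$k)
    next_id$k <- next_id$k + 1L
    members[[id]] <<- copies[copies > 0]
    id
  }
  one_per <- function(p) setNames(rep(1L, length(p)), p)

  for (i in seq_len(spec$n_true_scos)) {
    id <- add_cluster(one_per(proteomes))
    truth$true_scos <- c(truth$true_scos, id)
  }
  n_dup <- max(1L, as.integer(floor(n * 0.25))) # <= 25% duplicated proteomes
  for (i in seq_len(spec$n_fuzzy_extra)) {
    copies <- one_per(proteomes)
    copies[sample(proteomes, n_dup)] <- 2L
    add_cluster(copies)
  }
  for (lab in names(nodes)) {
    if (lab == "n0") next
    for (i in seq_len(spec$synapomorphies_per_node)) {
      add_cluster(one_per(nodes[[lab]]$leaves))
    }
  }
  for (p in proteomes) {
    for (i in seq_len(spec$n_specific_per_proteome)) {
      add_cluster(setNames(sample(2:3, 1), p))
    }
  }
  for (i in seq_len(spec$n_shared_random)) {
    k <- sample(2:n, 1)
    sub <- sample(proteomes, k)
    add_cluster(setNames(sample(1:3, k, replace = TRUE), sub))
  }
  for (p in proteomes) {
    for (i in seq_len(spec$n_singletons_per_proteome)) {
      add_cluster(setNames(1L, p))
    }
  }

  ## -- protein IDs: <proteome>_g<k>, numbered per proteome in cluster order
  prot_counter <- setNames(rep(0L, n), proteomes)
  clustering_rows <- lapply(names(members), function(id) {
    copies <- members[[id]]
    prots <- unlist(lapply(names(copies), function(p) {
      ks <- prot_counter[[p]] + seq_len(copies[[p]])
      prot_counter[[p]] <<- prot_counter[[p]] + copies[[p]]
      sprintf("%s_g%04d", p, ks)
    }))
    tibble(
      cluster_id = id,
      proteome_id = rep(names(copies), copies),
      protein_id = prots
    )
  })
  clustering <- bind_rows(clustering_rows)

  ## -- ground truth by direct rule application (independent of analysis code)
  copy_mat <- members
  sizes <- vapply(copy_mat, sum, integer(1))
  nprot <- vapply(copy_mat, length, integer(1))
  truth$n_clusters <- length(copy_mat)
  truth$singletons <- names(copy_mat)[sizes == 1]
  truth$nonsingleton_specific <- names(copy_mat)[sizes >= 2 & nprot == 1]
  truth$shared <- names(copy_mat)[nprot >= 2]
  truth$fuzzy_scos <- names(copy_mat)[vapply(copy_mat, function(cc) {
    full <- c(cc, setNames(rep(0L, n - length(cc)), setdiff(proteomes, names(cc))))
    all(full >= 1) && all(full <= 2) && sum(full == 1) >= ceiling(0.75 * n - 1e-9)
  }, logical(1))]

  # Dollo rule, evaluated against the generator's own node records
  syn_rows <- lapply(names(copy_mat), function(id) {
    mem <- names(copy_mat[[id]])
    if (length(mem) < 2) return(NULL)
    for (lab in names(nodes)) {
      nd <- nodes[[lab]]
      if (all(mem %in% nd$leaves) &&
          any(mem %in% nd$left) && any(mem %in% nd$right) &&
          # MRCA: no child subtree contains all members
          !all(mem %in% nd$left) && !all(mem %in% nd$right)) {
        cov <- length(mem) / length(nd$leaves)
        return(tibble(
          cluster_id = id, node = lab, coverage = cov,
          class = if (cov == 1) "complete_presence"
                  else if (cov >= 0.75) "partial_absence"
                  else "below_threshold"
        ))
      }
    }
    NULL
  })
  truth$synapomorphies <- bind_rows(syn_rows)

  ## -- lengths and sequences
  lengths <- tibble(
    protein_id = clustering$protein_id,
    length = pmax(50L, as.integer(round(rnorm(nrow(clustering),
                                              spec$length_mean, spec$length_sd))))
  )

  ## -- annotation: dedicated full-coverage implant on a cluster subset
  nonsingleton <- names(copy_mat)[sizes >= 2]
  n_implant <- round(spec$ipr_fraction * length(nonsingleton))
  implanted <- sort(sample(nonsingleton, n_implant))
  truth$representative_ipr_clusters <- implanted
  ann_rows <- list()
  for (i in seq_along(implanted)) {
    prots <- clustering$protein_id[clustering$cluster_id == implanted[i]]
    ann_rows[[length(ann_rows) + 1]] <- tibble(
      protein_id = prots,
      analysis = "Pfam",
      sig = sprintf("PF9%04d", i),
      sig_desc = sprintf("Implanted domain %d", i),
      ipr = sprintf("IPR9%05d", i),
      ipr_desc = sprintf("Implanted family %d", i),
      go = sprintf("GO:%07d", i)
    )
  }
  # namespace noise: random Pfam-only hits, never IPR
  noise_prots <- sample(clustering$protein_id, round(0.2 * nrow(clustering)))
  if (length(noise_prots) > 0) {
    ann_rows[[length(ann_rows) + 1]] <- tibble(
      protein_id = noise_prots,
      analysis = "Pfam",
      sig = sprintf("PF0%04d", sample.int(30, length(noise_prots), replace = TRUE)),
      sig_desc = "Noise domain", ipr = "-", ipr_desc = "-", go = "-"
    )
  }
  secreted <- sample(clustering$protein_id,
                     round(spec$secreted_fraction * nrow(clustering)))
  truth$secreted_proteins <- sort(secreted)
  if (length(secreted) > 0) {
    ann_rows[[length(ann_rows) + 1]] <- tibble(
      protein_id = secreted, analysis = "SignalP_EUK", sig = "SignalP-noTM",
      sig_desc = "Signal peptide", ipr = "-", ipr_desc = "-", go = "-"
    )
  }
  ann_raw <- bind_rows(ann_rows)

  ## -- config with clade attribute (root split) and TAXIDs
  root <- nodes[["n0"]]
  clade <- ifelse(proteomes %in% root$left, "cladeL", "cladeR")
  taxids <- 100L + seq_len(n)
  config <- tibble(proteome_id = proteomes, clade = clade,
                   TAXID = as.character(taxids))
  config$all <- "all"
  config$TAXON <- config$proteome_id
  attr(config, "attributes") <- config_attributes(config)
  # mini taxonomy: species -> genus (pairs) -> order (halves) -> phylum -> root
  genus_of <- 30L + (seq_len(n) - 1L) %/% 2L
  order_of <- ifelse(proteomes %in% root$left, 20L, 21L)
  # a genus inherits the order of its first member; species follow their genus
  genus_order <- order_of[2L * (genus_of - 30L) + 1L]
  truth$rank_levels <- tibble(
    proteome_id = proteomes,
    phylum = "Synthphyla",
    order = sprintf("Synthorder%s", ifelse(genus_order == 20L, "A", "B")),
    genus = sprintf("Synthgenus%02d", genus_of - 29L)
  )

  ## -- sequence map (tokens in proteome-major order)
  seqmap <- clustering |>
    arrange(match(.data$proteome_id, proteomes), .data$protein_id) |>
    group_by(.data$proteome_id) |>
    mutate(token = sprintf("%d_%d", match(.data$proteome_id[1], proteomes) - 1L,
                           row_number() - 1L)) |>
    ungroup() |>
    select("token", "protein_id", "proteome_id")

  out <- list(
    clustering = clustering, seqmap = seqmap, config = config,
    lengths = lengths,
    annotations = NULL, # filled from the written dialect below
    tree_newick = newick, manifest = truth, dir = dir, paths = NULL
  )

  ann_tsv <- interproscan_lines(ann_raw, lengths)
  out$annotations <- read_interproscan_lines(ann_tsv)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "fasta"), showWarnings = FALSE)
    dir.create(file.path(dir, "taxdump"), showWarnings = FALSE)
    p <- list(
      clustering = file.path(dir, "Orthogroups.txt"),
      seqids = file.path(dir, "SequenceIDs.txt"),
      config = file.path(dir, "config.csv"),
      annotations = file.path(dir, "annotations.tsv"),
      tree = file.path(dir, "tree.nwk"),
      nodes_dmp = file.path(dir, "taxdump", "nodes.dmp"),
      names_dmp = file.path(dir, "taxdump", "names.dmp"),
      fasta = file.path(dir, "fasta", paste0(proteomes, ".faa"))
    )
    token_of <- setNames(seqmap$token, seqmap$protein_id)
    ids <- unique(clustering$cluster_id)
    og_lines <- vapply(ids, function(id) {
      paste0(id, ": ",
             paste(token_of[clustering$protein_id[clustering$cluster_id == id]],
                   collapse = " "))
    }, character(1))
    writeLines(og_lines, p$clustering)
    writeLines(sprintf("%s: %s", seqmap$token, seqmap$protein_id), p$seqids)
    writeLines(c("#IDX,TAXON,clade,TAXID",
                 sprintf("%d,%s,%s,%s", seq_len(n) - 1L, proteomes, clade, taxids)),
               p$config)
    writeLines(ann_tsv, p$annotations)
    writeLines(newick, p$tree)
    write_mini_taxdump(p$nodes_dmp, p$names_dmp, proteomes, taxids,
                       genus_of, order_of, truth$rank_levels)
    len_of <- setNames(lengths$length, lengths$protein_id)
    residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
    for (i in seq_len(n)) {
      prots <- sort(clustering$protein_id[clustering$proteome_id == proteomes[i]])
      fasta <- unlist(lapply(prots, function(pr) {
        body <- paste(sample(residues, len_of[[pr]] - 1L, replace = TRUE),
                      collapse = "")
        c(paste0(">", pr, " synthetic"), paste0("M", body, "*"))
      }))
      writeLines(fasta, p$fasta[i])
    }
    out$paths <- p
  }
  invisible(out)
}

# InterProScan 14-column dialect rows for the fabricated annotation table
interproscan_lines <- function(ann_raw, lengths) {
  len_of <- setNames(lengths$length, lengths$protein_id)
  stopifnot(all(ann_raw$protein_id %in% names(len_of)))
  sprintf(
    "%s\t%s\t%d\t%s\t%s\t%s\t1\t%d\t1.0E-10\tT\t01-01-2020\t%s\t%s\t%s",
    ann_raw$protein_id, strrep("0", 32), len_of[ann_raw$protein_id],
    ann_raw$analysis, ann_raw$sig, ann_raw$sig_desc,
    len_of[ann_raw$protein_id], ann_raw$ipr, ann_raw$ipr_desc, ann_raw$go
  )
}

read_interproscan_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  read_interproscan(tf)
}

write_mini_taxdump <- function(nodes_path, names_path, proteomes, taxids,
                               genus_of, order_of, rank_levels) {
  row <- function(id, parent, rank) sprintf("%d\t|\t%d\t|\t%s\t|", id, parent, rank)
  nrow_ <- c(
    row(1L, 1L, "no rank"),
    row(10L, 1L, "phylum"),
    row(20L, 10L, "order"), row(21L, 10L, "order"),
    vapply(unique(genus_of), function(g) {
      parent <- order_of[match(g, genus_of)]
      row(g, parent, "genus")
    }, character(1)),
    vapply(seq_along(taxids), function(i) row(taxids[i], genus_of[i], "species"),
           character(1))
  )
  writeLines(nrow_, nodes_path)
  nm <- function(id, name) sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", id, name)
  names_lines <- c(
    nm(1L, "root"), nm(10L, "Synthphyla"),
    nm(20L, "SynthorderA"), nm(21L, "SynthorderB"),
    vapply(unique(genus_of), function(g) {
      nm(g, sprintf("Synthgenus%02d", g - 29L))
    }, character(1)),
    vapply(seq_along(taxids), function(i) {
      nm(taxids[i], paste0("Species ", proteomes[i]))
    }, character(1))
  )
  writeLines(names_lines, names_path)
}

#' The three-proteome worked example bundle
#'
#' A small, fully hand-checkable clustering over proteomes `A` (proteins
#' a1-a5), `B` (b1-b4) and `C` (c1-c3): `OG0 = {a1,b1,c1}`, `OG1 = {a2,b2}`,
#' `OG2 = {a3,a4}`, `OG3 = {b3}`, `OG4 = {a5,b4,c2}`, `OG5 = {c3}`. It has 6
#' clusters, 2 singletons, one proteome-specific nonsingleton cluster, two
#' strict single-copy orthologs, and co-occurrence weight 3 between A and B
#' (1 when universal clusters are excluded). The config defines a `host`
#' attribute (`A`,`B` = human; `C` = other) and the tree is `((A,B),C);`.
#'
#' @param dir Optional directory; when given, all input files are written
#'   there in their external dialects.
#' @return A list with `clustering`, `seqmap`, `config`, `lengths`,
#'   `annotations`, `tree_newick`, and `paths` (when `dir` was given).
#' @export
toy3_fixture <- function(dir = NULL) {
  clustering <- tibble(
    cluster_id = c("OG0", "OG0", "OG0", "OG1", "OG1", "OG2", "OG2",
                   "OG3", "OG4", "OG4", "OG4", "OG5"),
    proteome_id = c("A", "B", "C", "A", "B", "A", "A",
                    "B", "A", "B", "C", "C"),
    protein_id = c("a1", "b1", "c1", "a2", "b2", "a3", "a4",
                   "b3", "a5", "b4", "c2", "c3")
  )
  proteomes <- c("A", "B", "C")
  prots <- list(A = paste0("a", 1:5), B = paste0("b", 1:4), C = paste0("c", 1:3))
  seqmap <- bind_rows(lapply(seq_along(proteomes), function(i) {
    tibble(
      token = sprintf("%d_%d", i - 1L, seq_along(prots[[i]]) - 1L),
      protein_id = prots[[i]],
      proteome_id = proteomes[i]
    )
  }))
  config <- tibble(proteome_id = proteomes, host = c("human", "human", "other"))
  config$all <- "all"
  config$TAXON <- config$proteome_id
  attr(config, "attributes") <- config_attributes(config)
  lengths <- tibble(
    protein_id = c(prots$A, prots$B, prots$C),
    length = c(100L, 200L, 150L, 250L, 300L, 120L, 180L, 90L, 210L, 130L, 110L, 140L)
  )
  ann_raw <- tibble(
    protein_id = c("a1", "b1", "c1", "a5", "b4"),
    analysis = c("Pfam", "Pfam", "Pfam", "SignalP_EUK", "SignalP_EUK"),
    sig = c("PF00001", "PF00001", "PF00001", "SignalP-noTM", "SignalP-noTM"),
    sig_desc = c(rep("Toy domain", 3), rep("Signal peptide", 2)),
    ipr = c("IPR000001", "IPR000001", "IPR000001", "-", "-"),
    ipr_desc = c(rep("Toy family", 3), "-", "-"),
    go = c("GO:0005524", "GO:0005524", "GO:0005524", "-", "-")
  )
  ann_tsv <- interproscan_lines(ann_raw, lengths)
  out <- list(
    clustering = clustering, seqmap = seqmap, config = config,
    lengths = lengths, annotations = read_interproscan_lines(ann_tsv),
    tree_newick = "((A,B),C);", paths = NULL
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "fasta"), showWarnings = FALSE)
    p <- list(
      clustering = file.path(dir, "Orthogroups.txt"),
      seqids = file.path(dir, "SequenceIDs.txt"),
      config = file.path(dir, "config.csv"),
      annotations = file.path(dir, "annotations.tsv"),
      tree = file.path(dir, "tree.nwk"),
      fasta = file.path(dir, "fasta", paste0(proteomes, ".faa"))
    )
    token_of <- setNames(seqmap$token, seqmap$protein_id)
    ids <- unique(clustering$cluster_id)
    writeLines(vapply(ids, function(id) {
      paste0(id, ": ",
             paste(token_of[clustering$protein_id[clustering$cluster_id == id]],
                   collapse = " "))
    }, character(1)), p$clustering)
    writeLines(sprintf("%s: %s", seqmap$token, seqmap$protein_id), p$seqids)
    writeLines(c("#IDX,TAXON,host", paste(0:2, proteomes, config$host, sep = ",")),
               p$config)
    writeLines(ann_tsv, p$annotations)
    writeLines(out$tree_newick, p$tree)
    len_of <- setNames(lengths$length, lengths$protein_id)
    for (i in seq_along(proteomes)) {
      fasta <- unlist(lapply(prots[[i]], function(pr) {
        c(paste0(">", pr), paste0("M", strrep("K", len_of[[pr]] - 1L), "*"))
      }))
      writeLines(fasta, p$fasta[i])
    }
    out$paths <- p
  }
  out
}
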