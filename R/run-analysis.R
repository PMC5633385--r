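#' Run the full cluster analysis and write an output tree
#'
#' Orchestrates the whole pipeline: parses all inputs, then writes one
#' subdirectory per config attribute (cluster types, level summaries,
#' rarefaction curves, pairwise representation tests with volcano plots)
#' plus global outputs: the cluster size distribution with its power-law
#' reference fit, per-cluster metrics, the proteome co-occurrence GraphML,
#' strict and fuzzy single-copy ortholog lists, representative annotation
#' tables per namespace, and — when a tree is given — Dollo synapomorphy and
#' node summary tables. Tabular outputs use the `#`-headed TSV dialect of
#' [write_kf_tsv()]; re-running with identical inputs and seed reproduces
#' them byte for byte. A `run.log` records parameters and timings.
#'
#' @param clustering_path Orthogroups-format cluster file (required).
#' @param config_path Attribute config CSV (required).
#' @param sequence_ids_path SequenceIDs.txt; optional if the cluster file
#'   uses raw protein IDs and `fasta_paths` identify proteomes.
#' @param annotation_path Optional InterProScan TSV.
#' @param fasta_paths Optional character vector of proteome FASTA files.
#' @param tree_path Optional Newick file (or string) of the proteome tree.
#' @param outgroups Outgroup proteome IDs used to root the tree.
#' @param taxdump_nodes,taxdump_names Optional `nodes.dmp`/`names.dmp` paths;
#'   with a `TAXID` config column these add rank attributes.
#' @param ranks Taxonomy ranks to expand (default phylum, order, genus).
#' @param test_method Representation test (`"mwu"`, `"welch"`, `"student"`).
#' @param fuzzy_target_count,fuzzy_target_fraction,fuzzy_min,fuzzy_max
#'   Fuzzy single-copy parameters (see [find_fuzzy_scos()]).
#' @param domain_taxon_cov,domain_protein_cov Representative-annotation
#'   coverage thresholds.
#' @param node_taxon_cov Synapomorphy coverage threshold.
#' @param reps Rarefaction repetitions.
#' @param seed Seed for rarefaction sampling.
#' @param plot_format `"png"` or `"svg"`; `"none"` disables plots.
#' @param out_dir Output directory (created).
#' @return Invisibly, a named list of the computed tables.
#' @export
run_analysis <- function(clustering_path, config_path,
                         sequence_ids_path = NULL,
                         annotation_path = NULL, fasta_paths = NULL,
                         tree_path = NULL, outgroups = NULL,
                         taxdump_nodes = NULL, taxdump_names = NULL,
                         ranks = c("phylum", "order", "genus"),
                         test_method = c("mwu", "welch", "student"),
                         fuzzy_target_count = 1L, fuzzy_target_fraction = 0.75,
                         fuzzy_min = 1L, fuzzy_max = 2L,
                         domain_taxon_cov = 0.75, domain_protein_cov = 0.75,
                         node_taxon_cov = 0.75,
                         reps = 30, seed = 1,
                         plot_format = c("png", "svg", "none"),
                         out_dir) {
  test_method <- match.arg(test_method)
  plot_format <- match.arg(plot_format)
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("clusterkin %s", as.character(utils::packageVersion("clusterkin"))),
    sprintf("started: %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    sprintf("test_method=%s reps=%d seed=%d", test_method, reps, seed),
    sprintf("fuzzy: target_count=%d target_fraction=%g min=%d max=%d",
            fuzzy_target_count, fuzzy_target_fraction, fuzzy_min, fuzzy_max),
    sprintf("coverage: domain_taxon=%g domain_protein=%g node_taxon=%g",
            domain_taxon_cov, domain_protein_cov, node_taxon_cov)
  )

  config <- read_attribute_config(config_path)
  if (!is.null(taxdump_nodes) && !is.null(taxdump_names)) {
    if ("TAXID" %in% names(config)) {
      config <- expand_taxonomy_ranks(config, taxdump_nodes, taxdump_names, ranks)
    } else {
      warn("taxdump given but config has no TAXID column; ranks skipped")
    }
  }
  seqmap <- NULL
  if (!is.null(sequence_ids_path)) {
    seqmap <- read_sequence_ids(sequence_ids_path, config$proteome_id)
  }
  clustering <- read_clustering(clustering_path, seqmap = seqmap)
  lengths <- NULL
  if (!is.null(fasta_paths)) lengths <- read_fasta_lengths(fasta_paths)
  annotations <- NULL
  if (!is.null(annotation_path)) annotations <- read_interproscan(annotation_path)

  results <- list(config = config, clustering = clustering)
  save_plot <- function(p, stem) {
    if (plot_format == "none") return(invisible(NULL))
    path <- file.path(dirname(stem), paste0(basename(stem), ".", plot_format))
    tryCatch(
      suppressMessages(ggplot2::ggsave(
        path, p, width = 7, height = 5,
        device = if (plot_format == "svg") grDevices::svg else "png", dpi = 150
      )),
      error = function(e) warn(sprintf("could not write plot %s: %s", path,
                                       conditionMessage(e)))
    )
    invisible(NULL)
  }

  ## global outputs
  dist <- cluster_size_distribution(clustering)
  write_kf_tsv(dist, file.path(out_dir, "cluster_size_distribution.tsv"))
  pl_fit <- fit_power_law(dist)
  write_kf_tsv(glance(pl_fit), file.path(out_dir, "cluster_size_powerlaw.tsv"))
  save_plot(plot_cluster_sizes(dist, pl_fit),
            file.path(out_dir, "cluster_size_distribution"))
  results$size_distribution <- dist
  results$powerlaw <- pl_fit

  metrics <- cluster_metrics(clustering, lengths, annotations)
  if (!is.null(annotations)) {
    for (ns in c("Pfam", "IPR", "GO")) {
      if (ns %in% annotations$source) {
        ent <- annotation_entropy(clustering, annotations, ns)
        metrics[[paste0("entropy_", ns)]] <- ent$entropy
      }
    }
  }
  write_kf_tsv(metrics, file.path(out_dir, "cluster_metrics.tsv"))
  results$metrics <- metrics

  edges <- cooccurrence_edges(clustering, proteomes = config$proteome_id)
  write_cooccurrence_graphml(edges, file.path(out_dir, "cooccurrence.graphml"),
                             proteomes = config$proteome_id)
  results$cooccurrence <- edges

  true_scos <- find_true_scos(clustering, config$proteome_id)
  writeLines(true_scos$cluster_id, file.path(out_dir, "single_copy.true.txt"))
  fuzzy_scos <- find_fuzzy_scos(clustering, fuzzy_target_count,
                                fuzzy_target_fraction, fuzzy_min, fuzzy_max,
                                proteomes = config$proteome_id)
  writeLines(fuzzy_scos$cluster_id, file.path(out_dir, "single_copy.fuzzy.txt"))
  results$true_scos <- true_scos
  results$fuzzy_scos <- fuzzy_scos

  if (!is.null(annotations)) {
    for (ns in unique(annotations$source)) {
      rep_ann <- representative_annotation(clustering, annotations,
                                           domain_taxon_cov, domain_protein_cov,
                                           namespace = ns)
      write_kf_tsv(rep_ann,
                   file.path(out_dir, sprintf("cluster_domain_annotation.%s.tsv", ns)))
    }
    results$representative_annotation <-
      representative_annotation(clustering, annotations,
                                domain_taxon_cov, domain_protein_cov)
  }

  ## per-attribute outputs
  results$attributes <- list()
  for (attr_name in config_attributes(config)) {
    adir <- file.path(out_dir, attr_name)
    dir.create(adir, showWarnings = FALSE)
    types <- classify_clusters(clustering, config, attr_name)
    counts <- cluster_level_counts(clustering, config, attr_name)
    write_kf_tsv(left_join(types, counts, by = "cluster_id"),
                 file.path(adir, sprintf("%s.cluster_types.tsv", attr_name)))
    summ <- level_summary(clustering, config, attr_name)
    write_kf_tsv(summ, file.path(adir, sprintf("%s.level_summary.tsv", attr_name)))
    curve <- rarefaction_curve(clustering, config, attr_name, reps = reps, seed = seed)
    write_kf_tsv(curve, file.path(adir, sprintf("%s.rarefaction.tsv", attr_name)))
    save_plot(plot_rarefaction(curve), file.path(adir, sprintf("%s.rarefaction", attr_name)))

    levels <- unique(config[[attr_name]])
    if (length(levels) >= 2 && attr_name != "TAXON" && attr_name != "all") {
      pairs <- combn(levels, 2)
      for (j in seq_len(ncol(pairs))) {
        la <- pairs[1, j]; lb <- pairs[2, j]
        rt <- representation_test(clustering, config, attr_name, la, lb, test_method)
        if (nrow(rt) == 0) next
        vt <- volcano_table(rt)
        write_kf_tsv(select(vt, -"counts_a", -"counts_b"),
                     file.path(adir, sprintf("%s.%s-vs-%s.representation.tsv",
                                             attr_name, la, lb)))
        save_plot(plot_volcano(vt),
                  file.path(adir, sprintf("%s.%s-vs-%s.volcano", attr_name, la, lb)))
      }
    }
    results$attributes[[attr_name]] <- list(types = types, summary = summ)
  }

  ## phylogeny-aware outputs
  if (!is.null(tree_path)) {
    tree <- read_tree_topology(tree_path, outgroups = outgroups,
                               proteomes = config$proteome_id)
    syn <- infer_synapomorphies(clustering, tree, node_taxon_cov)
    write_kf_tsv(syn, file.path(out_dir, "tree.synapomorphies.tsv"))
    node_summ <- node_annotation_summary(syn, clustering, tree, annotations,
                                         domain_taxon_cov, domain_protein_cov,
                                         namespace = if (is.null(annotations)) NULL else "IPR")
    write_kf_tsv(node_summ, file.path(out_dir, "tree.node_summary.tsv"))
    apo <- list_apomorphies(clustering)
    write_kf_tsv(apo, file.path(out_dir, "tree.apomorphies.tsv"))
    results$tree <- tree
    results$synapomorphies <- syn
    results$node_summary <- node_summ
    results$apomorphies <- apo
  } else {
    log_lines <- c(log_lines, "no tree supplied: phylogeny outputs skipped")
  }

  log_lines <- c(log_lines, sprintf(
    "finished in %.2f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(results)
}
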