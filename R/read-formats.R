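#' Read an OrthoFinder SequenceIDs.txt file
#'
#' SequenceIDs files map internal sequence tokens of the form
#' `<proteomeIdx>_<seqIdx>` to protein accessions. Proteome indices are 0-based
#' and are resolved to proteome IDs through `proteome_ids`, whose order must
#' match the order in which the proteome FASTA files were given to the
#' clustering tool (the row order of the attribute config).
#'
#' @param path Path to a SequenceIDs.txt file (`<i>_<j>: <proteinID>` lines).
#' @param proteome_ids Character vector of proteome IDs in clustering input
#'   order.
#' @return A tibble with columns `token`, `protein_id`, `proteome_id`.
#' @examples
#' tf <- tempfile()
#' writeLines(c("0_0: A_prot1", "1_0: B_prot1"), tf)
#' read_sequence_ids(tf, c("A", "B"))
#' @export
read_sequence_ids <- function(path, proteome_ids) {
  lines <- read_nonempty_lines(path)
  keep <- which(nzchar(trimws(lines)))
  m <- regmatches(lines[keep], regexec("^(\\d+)_(\\d+):\\s*(\\S+)\\s*$", lines[keep]))
  bad <- which(lengths(m) == 0)
  if (length(bad) > 0) {
    parse_abort(path, keep[bad[1]], sprintf("malformed SequenceIDs line: %s", lines[keep[bad[1]]]))
  }
  token <- vapply(m, function(x) paste0(x[2], "_", x[3]), character(1))
  idx <- as.integer(vapply(m, `[`, character(1), 2))
  protein_id <- vapply(m, `[`, character(1), 4)
  if (anyDuplicated(token)) {
    dup <- token[duplicated(token)][1]
    abort(sprintf("%s: duplicate sequence token '%s'", path, dup), class = "clusterkin_parse_error")
  }
  if (anyDuplicated(protein_id)) {
    dup <- protein_id[duplicated(protein_id)][1]
    abort(sprintf("%s: duplicate protein ID '%s'", path, dup), class = "clusterkin_parse_error")
  }
  if (any(idx + 1L > length(proteome_ids))) {
    abort(sprintf(
      "%s: proteome index %d out of range for %d configured proteomes",
      path, max(idx), length(proteome_ids)
    ), class = "clusterkin_parse_error")
  }
  tibble(token = token, protein_id = protein_id, proteome_id = proteome_ids[idx + 1L])
}

#' Read an orthology clustering (Orthogroups.txt dialect)
#'
#' Each line is `<clusterID>: <member> <member> ...`. Members may be either
#' internal sequence tokens (`0_0`, resolved through `seqmap`) or raw protein
#' IDs; the dialect is auto-detected from the first member of the file.
#' Singleton clusters (one member) are retained.
#'
#' @param path Path to the cluster file.
#' @param seqmap A sequence map from [read_sequence_ids()]. May be `NULL` only
#'   when members are raw protein IDs, in which case `protein_proteomes` must
#'   be supplied.
#' @param protein_proteomes Optional tibble with columns `protein_id`,
#'   `proteome_id` used to resolve raw-ID cluster files without a sequence map.
#' @param infer_singletons If `TRUE`, proteins present in `seqmap` but absent
#'   from the cluster file are appended as synthetic singleton clusters with
#'   IDs `singleton_<k>`. Default `FALSE`.
#' @return A clustering tibble with one row per member protein and columns
#'   `cluster_id`, `proteome_id`, `protein_id`.
#' @export
read_clustering <- function(path, seqmap = NULL, protein_proteomes = NULL,
                            infer_singletons = FALSE) {
  lines <- read_nonempty_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    abort(sprintf("%s: no cluster lines found", path), class = "clusterkin_parse_error")
  }
  sp <- regmatches(lines[keep], regexpr(":", lines[keep]), invert = TRUE)
  bad <- which(lengths(sp) != 2)
  if (length(bad) > 0) {
    parse_abort(path, keep[bad[1]], "expected '<clusterID>: <member> ...'")
  }
  cluster_id <- trimws(vapply(sp, `[`, character(1), 1))
  members <- strsplit(trimws(vapply(sp, `[`, character(1), 2)), "\\s+")
  empty <- which(vapply(members, function(x) length(x) == 0 || all(!nzchar(x)), logical(1)))
  if (length(empty) > 0) {
    parse_abort(path, keep[empty[1]], sprintf("cluster '%s' has no members", cluster_id[empty[1]]))
  }
  if (anyDuplicated(cluster_id)) {
    dup <- cluster_id[duplicated(cluster_id)][1]
    abort(sprintf("%s: duplicate cluster ID '%s'", path, dup), class = "clusterkin_parse_error")
  }
  long <- tibble(
    cluster_id = rep(cluster_id, lengths(members)),
    member = unlist(members),
    line = rep(keep, lengths(members))
  )

  lookup <- NULL
  if (!is.null(seqmap) && long$member[1] %in% seqmap$token) {
    lookup <- tibble(member = seqmap$token, protein_id = seqmap$protein_id,
                     proteome_id = seqmap$proteome_id)
  } else {
    src <- protein_proteomes
    if (is.null(src) && !is.null(seqmap)) {
      src <- seqmap[, c("protein_id", "proteome_id")]
    }
    if (is.null(src)) {
      abort("cluster file uses raw protein IDs but no protein-to-proteome mapping was given")
    }
    lookup <- tibble(member = src$protein_id, protein_id = src$protein_id,
                     proteome_id = src$proteome_id)
  }
  res <- left_join(long, lookup, by = "member")
  unknown <- which(is.na(res$proteome_id))
  if (length(unknown) > 0) {
    parse_abort(path, res$line[unknown[1]],
                sprintf("unknown sequence token or protein ID '%s'", res$member[unknown[1]]))
  }
  if (anyDuplicated(res$protein_id)) {
    dup <- res$protein_id[duplicated(res$protein_id)][1]
    abort(sprintf("%s: protein '%s' appears in more than one cluster", path, dup),
          class = "clusterkin_parse_error")
  }
  out <- res[, c("cluster_id", "proteome_id", "protein_id")]
  if (isTRUE(infer_singletons) && !is.null(seqmap)) {
    missing <- seqmap[!seqmap$protein_id %in% out$protein_id, ]
    if (nrow(missing) > 0) {
      out <- bind_rows(out, tibble(
        cluster_id = sprintf("singleton_%d", seq_len(nrow(missing))),
        proteome_id = missing$proteome_id,
        protein_id = missing$protein_id
      ))
    }
  }
  out
}

#' Write a clustering back to Orthogroups.txt format
#'
#' Inverse of [read_clustering()]; members are written as raw protein IDs.
#'
#' @param clustering A clustering tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, path) {
  assert_clustering(clustering)
  ids <- keep_cluster_order(clustering)
  members <- split(clustering$protein_id, factor(clustering$cluster_id, levels = ids))
  lines <- vapply(ids, function(id) {
    paste0(id, ": ", paste(members[[id]], collapse = " "))
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read the taxon-attribute config table
#'
#' A comma-delimited table whose first column (`#IDX` or `IDX`) is a row
#' index, second column (`TAXON`) holds the proteome ID, and remaining columns
#' define arbitrary attributes grouping the proteomes into taxon sets. An
#' optional `TAXID` column holds NCBI taxonomy IDs used by
#' [expand_taxonomy_ranks()]. Two reserved attributes are always injected:
#' `all` (every proteome in the single level `"all"`) and `TAXON` (each
#' proteome its own level).
#'
#' @param path Path to the config CSV.
#' @return A tibble with column `proteome_id`, one column per attribute, and,
#'   when present in the input, a `TAXID` column (not treated as an
#'   attribute). Attribute names are recorded in the `"attributes"` attribute.
#' @export
read_attribute_config <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(sub("^#", "", lines[1]), ",")[[1]]
  header <- trimws(header)
  if (length(header) < 2 || toupper(header[1]) != "IDX" || header[2] != "TAXON") {
    abort(sprintf("%s: config header must start with '#IDX,TAXON'", path),
          class = "clusterkin_parse_error")
  }
  rows <- strsplit(lines[-1], ",")
  badlen <- which(lengths(rows) != length(header))
  if (length(badlen) > 0) {
    parse_abort(path, badlen[1] + 1L, sprintf(
      "expected %d fields, found %d", length(header), lengths(rows)[badlen[1]]
    ))
  }
  mat <- do.call(rbind, lapply(rows, trimws))
  df <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE), .name_repair = "minimal")
  names(df) <- header
  df <- df[, -1, drop = FALSE]
  names(df)[1] <- "proteome_id"
  if (anyDuplicated(df$proteome_id)) {
    dup <- df$proteome_id[duplicated(df$proteome_id)][1]
    abort(sprintf("%s: duplicate proteome ID '%s'", path, dup), class = "clusterkin_parse_error")
  }
  if (any(!nzchar(as.matrix(df)))) {
    abort(sprintf("%s: empty cell in config table", path), class = "clusterkin_parse_error")
  }
  df$all <- "all"
  df$TAXON <- df$proteome_id
  attr(df, "attributes") <- config_attributes(df)
  df
}

#' Attribute names of a config table
#'
#' @param config A config tibble from [read_attribute_config()].
#' @return Character vector of attribute column names (`TAXID` and
#'   `proteome_id` excluded).
#' @export
config_attributes <- function(config) {
  setdiff(names(config), c("proteome_id", "TAXID"))
}

#' Taxon sets of one attribute
#'
#' Expands one attribute column of the config into a long level-to-proteome
#' table. The levels of an attribute partition the proteome list.
#'
#' @param config A config tibble.
#' @param attribute Attribute name.
#' @return A tibble with columns `level`, `proteome_id`.
#' @export
taxon_sets <- function(config, attribute) {
  if (!attribute %in% config_attributes(config)) {
    abort(sprintf("unknown attribute '%s'", attribute))
  }
  tibble(level = config[[attribute]], proteome_id = config$proteome_id)
}

# namespaces synthesized from dedicated InterProScan columns
.ipr_go_namespaces <- c("IPR", "GO")

#' Read InterProScan tab-separated annotation
#'
#' Parses the InterProScan TSV dialect (protein accession, MD5, length,
#' analysis, signature accession, signature description, start, stop, score,
#' status, date, and optionally InterPro accession, InterPro description and a
#' `|`-separated GO column). Each analysis value becomes an annotation
#' namespace verbatim (e.g. `Pfam`, `SignalP_EUK`); the InterPro accession
#' column is mapped to namespace `IPR` and GO terms to namespace `GO`.
#' Multiple hits of the same signature on one protein collapse to one record.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id`, `source`, `term_id`,
#'   `description`, unique over (protein, source, term).
#' @export
read_interproscan <- function(path) {
  lines <- read_nonempty_lines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  badlen <- which(lengths(rows) < 11)
  if (length(badlen) > 0) {
    parse_abort(path, keep[badlen[1]], sprintf(
      "expected >= 11 tab-separated columns, found %d", lengths(rows)[badlen[1]]
    ))
  }
  get_col <- function(i) vapply(rows, function(r) if (length(r) >= i) r[i] else "", character(1))
  protein <- get_col(1)
  analysis <- get_col(4)
  sig <- get_col(5)
  sig_desc <- get_col(6)
  ipr <- get_col(12)
  ipr_desc <- get_col(13)
  go <- get_col(14)

  recs <- list(
    tibble(protein_id = protein, source = analysis, term_id = sig, description = sig_desc)
  )
  has_ipr <- nzchar(ipr) & ipr != "-"
  if (any(has_ipr)) {
    recs <- c(recs, list(tibble(
      protein_id = protein[has_ipr], source = "IPR",
      term_id = ipr[has_ipr], description = ipr_desc[has_ipr]
    )))
  }
  has_go <- nzchar(go) & go != "-"
  if (any(has_go)) {
    go_terms <- strsplit(go[has_go], "|", fixed = TRUE)
    recs <- c(recs, list(tibble(
      protein_id = rep(protein[has_go], lengths(go_terms)),
      source = "GO",
      term_id = unlist(go_terms),
      description = ""
    )))
  }
  out <- bind_rows(recs)
  out <- out[nzchar(out$term_id) & out$term_id != "-", ]
  distinct(out, .data$protein_id, .data$source, .data$term_id, .keep_all = TRUE)
}

#' Protein lengths from proteome FASTA files
#'
#' Reads amino-acid FASTA files and records residue counts per protein. The
#' protein ID is the first whitespace-delimited token of the header; a
#' terminal stop character `*` is stripped before counting.
#'
#' @param paths Character vector of FASTA file paths.
#' @return A tibble with columns `protein_id`, `length` (residues).
#' @export
read_fasta_lengths <- function(paths) {
  per_file <- lapply(paths, function(p) {
    aa <- Biostrings::readAAStringSet(p)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
    seqs <- as.character(aa)
    seqs <- sub("\\*$", "", seqs)
    tibble(protein_id = ids, length = unname(nchar(seqs)))
  })
  out <- bind_rows(per_file)
  if (anyDuplicated(out$protein_id)) {
    dup <- out$protein_id[duplicated(out$protein_id)][1]
    abort(sprintf("duplicate protein ID across FASTA files: '%s'", dup),
          class = "clusterkin_parse_error")
  }
  if (any(out$length < 1)) {
    abort("zero-length sequence in FASTA input", class = "clusterkin_parse_error")
  }
  out
}
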