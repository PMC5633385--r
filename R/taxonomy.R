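#' Add taxonomy-rank attributes from an NCBI taxdump
#'
#' Resolves the `TAXID` column of the config against `nodes.dmp`/`names.dmp`
#' and injects one new attribute per requested rank, whose level is the
#' scientific name of the ancestor at that rank. Lineages lacking a rank, and
#' TaxIDs absent from the taxdump (warned), get level `"undef"`.
#'
#' @param config A config tibble with a `TAXID` column.
#' @param nodes_path Path to `nodes.dmp` (`"\t|\t"`-delimited).
#' @param names_path Path to `names.dmp`.
#' @param ranks Character vector of rank names. Default
#'   `c("phylum", "order", "genus")`.
#' @return The config tibble with one added column per rank.
#' @export
expand_taxonomy_ranks <- function(config, nodes_path, names_path,
                                  ranks = c("phylum", "order", "genus")) {
  if (!"TAXID" %in% names(config)) {
    abort("config has no TAXID column; cannot derive taxonomy ranks")
  }
  nodes <- parse_dmp(nodes_path)
  parent_of <- setNames(nodes[[2]], nodes[[1]])
  rank_of <- setNames(nodes[[3]], nodes[[1]])
  nm <- parse_dmp(names_path)
  nm <- nm[nm[[4]] == "scientific name", ]
  name_of <- setNames(nm[[2]], nm[[1]])

  lineage_level <- function(taxid, rank) {
    cur <- as.character(taxid)
    if (!cur %in% names(parent_of)) return(NA_character_)
    for (i in seq_len(100)) { # lineage depth guard
      if (identical(unname(rank_of[cur]), rank)) {
        return(unname(name_of[cur]) %||% "undef")
      }
      up <- unname(parent_of[cur])
      if (is.na(up) || up == cur) break
      cur <- up
    }
    "undef"
  }

  unknown <- !as.character(config$TAXID) %in% names(parent_of)
  if (any(unknown)) {
    warn(sprintf("TaxID(s) absent from taxdump: %s",
                 paste(unique(config$TAXID[unknown]), collapse = ", ")))
  }
  for (rank in ranks) {
    lv <- vapply(config$TAXID, lineage_level, character(1), rank = rank,
                 USE.NAMES = FALSE)
    config[[rank]] <- ifelse(is.na(lv), "undef", lv)
  }
  attr(config, "attributes") <- config_attributes(config)
  config
}

# read a taxdump .dmp table: fields separated by "\t|\t", trailing "\t|"
parse_dmp <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- sub("\t\\|$", "", lines)
  fields <- strsplit(lines, "\t|\t", fixed = TRUE)
  ncol <- max(lengths(fields))
  as.data.frame(
    do.call(rbind, lapply(fields, function(f) c(f, rep("", ncol - length(f))))),
    stringsAsFactors = FALSE
  )
}
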