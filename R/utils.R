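# shared internal helpers

# Stop with a parse-error message naming file and line.
parse_abort <- function(path, line_no, msg) {
  abort(sprintf("%s: line %d: %s", path, line_no, msg), class = "clusterkin_parse_error")
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "clusterkin_io_error")
  }
  readLines(path, warn = FALSE)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. If seed is NULL, uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Tab-separated output with a '#'-prefixed header row and UNIX newlines.
#' Write a table in the package's TSV dialect
#'
#' Writes a tab-delimited file with UNIX newlines whose header row is prefixed
#' with `#`, the convention used for all tabular outputs of
#' [run_analysis()].
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kf_tsv <- function(x, path) {
  x <- as.data.frame(x)
  list_cols <- vapply(x, is.list, logical(1))
  x[list_cols] <- lapply(x[list_cols], function(col) {
    vapply(col, function(v) paste(v, collapse = ","), character(1))
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste0("#", paste(names(x), collapse = "\t"), "\n")
  writeChar(header, con, eos = NULL)
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, format_cell), list(sep = "\t")))
    writeChar(paste0(paste(body, collapse = "\n"), "\n"), con, eos = NULL)
  }
  invisible(path)
}

format_cell <- function(v) {
  if (is.double(v)) {
    out <- ifelse(is.na(v), "N/A", formatC(v, format = "g", digits = 10))
  } else {
    out <- ifelse(is.na(v), "N/A", as.character(v))
  }
  out
}

#' Read a table written by [write_kf_tsv()]
#'
#' @param path File path.
#' @return A tibble; the leading `#` of the header row is stripped.
#' @export
read_kf_tsv <- function(path) {
  lines <- read_nonempty_lines(path)
  lines[1] <- sub("^#", "", lines[1])
  readr::read_tsv(I(lines), show_col_types = FALSE, na = "N/A", progress = FALSE)
}

# cluster_id levels in first-appearance order
keep_cluster_order <- function(clustering) {
  unique(clustering$cluster_id)
}

assert_clustering <- function(clustering) {
  need <- c("cluster_id", "proteome_id", "protein_id")
  if (!is.data.frame(clustering) || !all(need %in% names(clustering))) {
    abort("`clustering` must be a data frame with columns cluster_id, proteome_id, protein_id")
  }
  invisible(clustering)
}
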