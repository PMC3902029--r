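#' Read an interaction network from an edge-list file
#'
#' Supports two plain-text dialects: `"tsv"` (two or more whitespace/tab
#' separated columns; the first two are the edge endpoints, the rest are
#' ignored) and `"sif"` (node, relation, node, node, ...; one edge from the
#' first node to each node from the third column on). Lines starting with `#`
#' and blank lines are skipped. Duplicated edges are collapsed and self-loops
#' dropped; a load report (lines read, duplicates, self-loops) is emitted as a
#' message and attached to the result.
#'
#' @param path Path to the edge-list file.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @param quiet Suppress the load-report message.
#' @return An [interaction_graph()].
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  n_lines <- length(lines)
  content <- !grepl("^\\s*(#|$)", lines)
  idx <- which(content)
  if (length(idx) == 0) abort(sprintf("empty edge list: %s", path))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  min_fields <- if (dialect == "tsv") 2L else 3L
  bad <- nf < min_fields
  if (any(bad)) {
    abort(sprintf(
      "malformed %s line %d: expected >= %d fields, got %d",
      dialect, idx[which(bad)[1]], min_fields, nf[which(bad)[1]]
    ))
  }
  if (dialect == "tsv") {
    from <- vapply(fields, `[[`, character(1), 1L)
    to <- vapply(fields, `[[`, character(1), 2L)
  } else {
    from <- unlist(purrr::map(fields, function(f) rep(f[[1]], length(f) - 2L)))
    to <- unlist(purrr::map(fields, function(f) f[-(1:2)]))
  }
  g <- interaction_graph(tibble(from = from, to = to))
  rep <- attr(g, "load_report")
  rep$lines_read <- n_lines
  rep$comment_or_blank <- n_lines - length(idx)
  attr(g, "load_report") <- rep
  if (!quiet) {
    inform(sprintf(
      "read %d lines (%d comment/blank): %d edges kept, %d duplicates dropped, %d self-loops dropped",
      n_lines, rep$comment_or_blank, graph_size(g),
      rep$duplicates_dropped, rep$self_loops_dropped
    ))
  }
  g
}

#' Write a graph as a two-column TSV edge list
#'
#' Rows are the canonical (lexicographically ordered) edges, so writing and
#' re-reading reproduces the same graph byte-for-byte. No header line is
#' written: the file is directly re-readable by [read_edge_list()]. Isolated
#' nodes cannot be represented in an edge list and are dropped with a warning.
#'
#' @param g An [interaction_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "interaction_graph"))
  isolated <- setdiff(g$nodes, c(g$edges$from, g$edges$to))
  if (length(isolated) > 0) {
    warn(sprintf("%d isolated node(s) are not representable in an edge list and were dropped", length(isolated)))
  }
  writeLines(paste(g$edges$from, g$edges$to, sep = "\t"), path)
  invisible(path)
}

#' Write and read a zone-assignment table
#'
#' The table has a `node<TAB>zone<TAB>degree` header and one row per
#' giant-component node (zone 0 = the centre member(s)), sorted by
#' `(zone, node)` so output is byte-reproducible. `header` lines, if given,
#' are written first as `#`-prefixed comments; [read_zone_table()] skips them.
#'
#' @param zones A [zone_decompose()] result.
#' @param path Output path.
#' @param header Optional character vector of comment lines (without the
#'   leading `#`).
#' @return `write_zone_table()` returns `path` invisibly; `read_zone_table()`
#'   returns a `zone_decomposition` tibble equal to the one written.
#' @export
write_zone_table <- function(zones, path, header = NULL) {
  stopifnot(inherits(zones, "zone_decomposition"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("node\tzone\tdegree", con)
  writeLines(paste(zones$node, zones$zone, zones$degree, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_zone_table
#' @export
read_zone_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2) abort(sprintf("zone table %s has no data rows", path))
  if (!identical(lines[[1]], "node\tzone\tdegree")) {
    abort(sprintf("unexpected zone-table header in %s", path))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0) abort(sprintf("malformed zone-table row %d in %s", bad[1] + 1L, path))
  tbl <- tibble(
    node = vapply(fields, `[[`, character(1), 1L),
    zone = as.integer(vapply(fields, `[[`, character(1), 2L)),
    degree = as.integer(vapply(fields, `[[`, character(1), 3L))
  )
  tbl <- tbl[order(tbl$zone, tbl$node), ]
  new_zone_decomposition(tbl, centre = tbl$node[tbl$zone == 0L])
}
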