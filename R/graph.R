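#' Build an undirected simple interaction graph
#'
#' The universal input container: an undirected simple graph over opaque,
#' case-sensitive string node identifiers. Self-loops are dropped (a protein
#' interacting with itself plays no role in distances), duplicate edges are
#' collapsed, and edge orientation is ignored, so directed inputs such as
#' signalling edges are symmetrised.
#'
#' @param edges A data frame whose first two columns are edge endpoints, or a
#'   two-column character matrix. Extra columns (confidence scores etc.) are
#'   ignored: all distances are unweighted.
#' @param nodes Optional character vector of additional node identifiers;
#'   isolated nodes not appearing in any edge are kept.
#'
#' @return An `interaction_graph`: a list with sorted `nodes` (character) and
#'   canonical `edges` (a tibble with columns `from` < `to`, lexicographically
#'   sorted). The object records how many self-loops and duplicates were
#'   dropped in the `load_report` attribute.
#' @examples
#' g <- interaction_graph(data.frame(a = c("A", "B", "A"), b = c("B", "A", "C")))
#' graph_order(g)
#' graph_size(g)
#' @export
interaction_graph <- function(edges, nodes = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    abort("`edges` must be a data frame (or matrix) with at least two columns")
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  if (anyNA(from) || anyNA(to)) abort("edge endpoints must not be NA")
  n_in <- length(from)
  loops <- from == to
  from2 <- from[!loops]
  to2 <- to[!loops]
  lo <- pmin(from2, to2)
  hi <- pmax(from2, to2)
  # paste0 recycles its "\r" separator to length 1 on empty input
  key <- if (length(lo) > 0) paste0(lo, "\r", hi) else character(0)
  keep <- !duplicated(key)
  edge_tbl <- tibble(from = lo[keep], to = hi[keep])
  edge_tbl <- edge_tbl[order(edge_tbl$from, edge_tbl$to), ]
  node_set <- sort(unique(c(edge_tbl$from, edge_tbl$to, as.character(nodes %||% character()))))
  structure(
    list(nodes = node_set, edges = edge_tbl),
    load_report = list(
      pairs_in = n_in,
      self_loops_dropped = sum(loops),
      duplicates_dropped = sum(!keep)
    ),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf(
    "<interaction_graph> %d nodes, %d edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Graph order, size, nodes and edges
#'
#' @param g An [interaction_graph()].
#' @return `graph_order()`/`graph_size()` return a single integer (number of
#'   nodes / edges); `graph_nodes()` the sorted node identifiers;
#'   `graph_edges()` the canonical edge tibble.
#' @export
graph_order <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  length(g$nodes)
}

#' @rdname graph_order
#' @export
graph_size <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  nrow(g$edges)
}

#' @rdname graph_order
#' @export
graph_nodes <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  g$nodes
}

#' @rdname graph_order
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  g$edges
}

#' Whole-graph node degrees
#'
#' @param g An [interaction_graph()].
#' @return A tibble with columns `node` and `degree`, sorted by node
#'   identifier. Degree sums to twice the edge count.
#' @export
node_degrees <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  idx <- c(
    match(g$edges$from, g$nodes),
    match(g$edges$to, g$nodes)
  )
  tibble(node = g$nodes, degree = tabulate(idx, nbins = length(g$nodes)))
}

# CSR adjacency (0-based) for the compiled BFS kernels.
graph_csr <- function(g) {
  n <- length(g$nodes)
  ei <- match(g$edges$from, g$nodes)
  ej <- match(g$edges$to, g$nodes)
  arc_from <- c(ei, ej)
  arc_to <- c(ej, ei)
  ord <- order(arc_from, arc_to)
  deg <- tabulate(arc_from, nbins = n)
  list(
    offsets = as.integer(c(0L, cumsum(deg))),
    targets = as.integer(arc_to[ord] - 1L)
  )
}

#' Induced subgraph on a node subset
#'
#' The subgraph inherits every edge of `g` whose two endpoints are both in
#' `nodes` (cross-boundary edges are dropped), matching the usual definition
#' of an induced subgraph.
#'
#' @param g An [interaction_graph()].
#' @param nodes Character vector of node identifiers; must all be in `g`.
#' @return An [interaction_graph()] over exactly `nodes` (isolated members kept).
#' @export
induced_subgraph_on <- function(g, nodes) {
  stopifnot(inherits(g, "interaction_graph"))
  nodes <- unique(as.character(nodes))
  missing <- setdiff(nodes, g$nodes)
  if (length(missing) > 0) {
    abort(sprintf(
      "nodes not in graph: %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  keep <- g$edges$from %in% nodes & g$edges$to %in% nodes
  interaction_graph(g$edges[keep, , drop = FALSE], nodes = nodes)
}

#' Drop a node set from a graph
#'
#' Convenience wrapper used e.g. to exclude a suspect dense complete subgraph
#' before hub analysis: returns the subgraph induced on all remaining nodes.
#'
#' @inheritParams induced_subgraph_on
#' @param exclude Character vector of node identifiers to remove.
#' @return An [interaction_graph()].
#' @export
exclude_nodes <- function(g, exclude) {
  induced_subgraph_on(g, setdiff(g$nodes, as.character(exclude)))
}
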