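#' Connected components of a graph
#'
#' Components are numbered by decreasing size, ties broken by the smallest
#' node identifier they contain, so the labelling is deterministic. The
#' largest component is the giant component; the analysis pipeline operates
#' on it only.
#'
#' @param g A non-empty [interaction_graph()].
#' @return A `component_decomposition`: a list with `membership` (tibble of
#'   `node`, `component`), `sizes` (integer vector indexed by component),
#'   `n_components`, and `giant` (character vector of the giant component's
#'   nodes).
#' @export
graph_components <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  if (graph_order(g) == 0) abort("graph is empty")
  csr <- graph_csr(g)
  raw <- cpp_components(csr$offsets, csr$targets) + 1L
  sizes <- tabulate(raw)
  # order components by size desc, then by smallest contained node id
  first_node <- g$nodes[match(seq_along(sizes), raw)]
  ord <- order(-sizes, first_node)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  comp <- relabel[raw]
  structure(
    list(
      membership = tibble(node = g$nodes, component = comp),
      sizes = sizes[ord],
      n_components = length(sizes),
      giant = sort(g$nodes[comp == 1L])
    ),
    class = "component_decomposition"
  )
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf(
    "<component_decomposition> %d component(s); giant component: %d of %d nodes\n",
    x$n_components, length(x$giant), nrow(x$membership)
  ))
  invisible(x)
}

#' Extract the giant component
#'
#' @param g An [interaction_graph()].
#' @param components Optional precomputed [graph_components()] result.
#' @return The subgraph induced on the largest component.
#' @export
giant_component <- function(g, components = NULL) {
  comps <- components %||% graph_components(g)
  stopifnot(inherits(comps, "component_decomposition"))
  induced_subgraph_on(g, comps$giant)
}

#' Exact all-pairs eccentricities, radius, diameter and centre
#'
#' The eccentricity of a node is its greatest hop distance to any other node.
#' Every edge has unit length, so one breadth-first search per source gives
#' the exact all-pairs answer the same shortest-path distances Dijkstra would
#' produce. The minimum eccentricity is the radius, the maximum the diameter,
#' and the nodes attaining the radius form the topological centre.
#'
#' @param g A connected [interaction_graph()] — call on the giant component.
#'   Disconnected input is an error (eccentricity is infinite across
#'   components), not silently restricted.
#' @return An `eccentricity_map` tibble with columns `node`, `eccentricity`
#'   and attributes `radius`, `diameter`, `centre` (sorted character vector).
#' @examples
#' p5 <- interaction_graph(data.frame(from = c("a", "b", "c", "d"),
#'                                    to   = c("b", "c", "d", "e")))
#' em <- node_eccentricities(p5)
#' attr(em, "radius"); attr(em, "centre")
#' @export
node_eccentricities <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  if (graph_order(g) == 0) abort("graph is empty")
  if (graph_order(g) == 1) {
    ecc <- 0L
  } else {
    csr <- graph_csr(g)
    ecc <- cpp_all_eccentricities(csr$offsets, csr$targets)
  }
  out <- tibble(node = g$nodes, eccentricity = as.integer(ecc))
  structure(
    out,
    radius = min(out$eccentricity),
    diameter = max(out$eccentricity),
    centre = sort(out$node[out$eccentricity == min(out$eccentricity)]),
    class = c("eccentricity_map", class(out))
  )
}

#' Topological centre of a graph
#'
#' All nodes attaining the radius are returned: the method reports multiple
#' centres when they exist, even though real interaction networks typically
#' show a single central protein.
#'
#' @param x An `eccentricity_map` from [node_eccentricities()], or a connected
#'   [interaction_graph()] (eccentricities are then computed first).
#' @return Sorted character vector of centre node identifiers (non-empty).
#' @export
graph_centre <- function(x) {
  if (inherits(x, "interaction_graph")) x <- node_eccentricities(x)
  stopifnot(inherits(x, "eccentricity_map"))
  attr(x, "centre")
}

new_zone_decomposition <- function(tbl, centre) {
  structure(
    as_tibble(tbl),
    centre = sort(unique(as.character(centre))),
    max_zone = max(tbl$zone),
    class = c("zone_decomposition", class(as_tibble(tbl)))
  )
}

#' Decompose a connected graph into distance zones around the centre
#'
#' Zone k is the set of nodes at hop distance exactly k from the nearest
#' centre node (multi-source breadth-first layering when the centre has more
#' than one member); zone 0 is the centre itself. Every giant-component node
#' therefore lands in exactly one zone, and adjacent nodes' zone indices
#' differ by at most one.
#'
#' @param g A connected [interaction_graph()].
#' @param centre Character vector of centre node identifiers; by default the
#'   topological centre computed by [node_eccentricities()].
#' @return A `zone_decomposition` tibble with columns `node`, `zone`,
#'   `degree` (whole-graph degree in `g`), sorted by `(zone, node)`, and
#'   attributes `centre` and `max_zone`.
#' @export
zone_decompose <- function(g, centre = NULL) {
  stopifnot(inherits(g, "interaction_graph"))
  centre <- centre %||% graph_centre(g)
  centre <- unique(as.character(centre))
  missing <- setdiff(centre, g$nodes)
  if (length(missing) > 0) {
    abort(sprintf("centre node(s) absent from graph: %s", paste(missing, collapse = ", ")))
  }
  if (length(centre) == 0) abort("`centre` must be non-empty")
  csr <- graph_csr(g)
  dist <- cpp_bfs_distances(csr$offsets, csr$targets, as.integer(match(centre, g$nodes) - 1L))
  if (any(dist < 0)) {
    abort("graph is disconnected: zones are defined on a connected graph; extract the giant component first")
  }
  deg <- node_degrees(g)
  tbl <- tibble(node = g$nodes, zone = as.integer(dist), degree = deg$degree)
  tbl <- tbl[order(tbl$zone, tbl$node), ]
  new_zone_decomposition(tbl, centre = centre)
}

#' @export
print.zone_decomposition <- function(x, ...) {
  cat(sprintf(
    "<zone_decomposition> %d nodes in zones 0..%d around centre {%s}\n",
    nrow(x), attr(x, "max_zone"), paste(attr(x, "centre"), collapse = ", ")
  ))
  NextMethod()
}
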