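#' Planted-centre core-periphery graph generator
#'
#' Builds a connected simple graph that emulates the topology of real
#' interaction networks: one designated centre node adjacent to every zone-1
#' node; each deeper node wired to at least one node of the previous zone
#' (which pins its distance from the centre to exactly its zone index);
#' within-zone edges added independently at a per-zone density that should
#' decrease outward; and per-zone counts of quills — nodes left with
#' whole-graph degree exactly 1. Non-quill nodes that would end up with
#' degree 1 by chance get one extra edge (to a second previous-zone node, or
#' failing that a within-zone partner), so the planted quill counts are exact
#' ground truth. The planted centre is required to be the unique topological
#' centre; candidates violating this are rejected and resampled (bounded
#' retries).
#'
#' Defaults plant three zones of sizes 50/200/100 with densities
#' 0.3/0.02/0 and quill counts 0/20/100 — a small-scale caricature of the
#' dense-core, quill-fringed shape of real networks, where the outermost zone
#' is pure quills.
#'
#' @param zone_sizes Integer vector, nodes per zone 1..Z (all >= 1).
#' @param intra_zone_density Per-zone probability of an edge between two
#'   non-quill members of the same zone; same length as `zone_sizes`,
#'   values in \[0, 1\].
#' @param quill_counts Per-zone number of planted quills; `quill_counts[k] <=
#'   zone_sizes[k]`, and every zone that feeds a deeper zone must keep at
#'   least one non-quill member.
#' @param seed Optional integer seed; generation is then a pure function of
#'   the arguments.
#' @param max_tries Rejection-sampling bound on centre-uniqueness retries.
#' @return A `planted_graph`: list with `graph` (an [interaction_graph()]),
#'   `centre` (the planted centre id, `"centre"`), `truth` (tibble `node`,
#'   `zone`, `is_quill` — the ground-truth zone and quill maps), and
#'   `attempts` (rejection-sampling tries used).
#' @examples
#' pg <- planted_core_periphery(c(3), 0, c(3), seed = 1)  # the star S4
#' graph_centre(pg$graph)
#' @export
planted_core_periphery <- function(zone_sizes = c(50, 200, 100),
                                   intra_zone_density = c(0.3, 0.02, 0),
                                   quill_counts = c(0, 20, 100),
                                   seed = NULL, max_tries = 100) {
  Z <- length(zone_sizes)
  if (Z == 0) abort("at least one zone is required")
  if (length(intra_zone_density) != Z || length(quill_counts) != Z) {
    abort("`zone_sizes`, `intra_zone_density` and `quill_counts` must have equal length")
  }
  if (any(zone_sizes < 1)) abort("every zone must have at least one node")
  if (any(intra_zone_density < 0 | intra_zone_density > 1)) abort("densities must be in [0, 1]")
  if (any(quill_counts < 0 | quill_counts > zone_sizes)) {
    abort("`quill_counts` must satisfy 0 <= quill_counts[k] <= zone_sizes[k]")
  }
  feeds_deeper <- seq_len(Z) < Z
  if (any(feeds_deeper & (zone_sizes - quill_counts) < 1)) {
    abort("infeasible spec: a zone feeding a deeper zone must keep >= 1 non-quill node to act as a parent")
  }
  build <- function() {
    for (attempt in seq_len(max_tries)) {
      cand <- build_planted_once(zone_sizes, intra_zone_density, quill_counts)
      em <- node_eccentricities(cand$graph)
      centre_set <- attr(em, "centre")
      if (identical(centre_set, "centre")) {
        cand$attempts <- attempt
        return(cand)
      }
    }
    abort(sprintf("could not realise a unique planted centre in %d tries; adjust the spec", max_tries))
  }
  out <- if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
  structure(out, class = "planted_graph")
}

build_planted_once <- function(zone_sizes, intra_zone_density, quill_counts) {
  Z <- length(zone_sizes)
  width <- max(4, nchar(as.character(max(zone_sizes))))
  zone_nodes <- purrr::map(seq_len(Z), function(k) {
    sprintf(paste0("z%d_n%0", width, "d"), k, seq_len(zone_sizes[k]))
  })
  # quills are the tail of each zone's node list; non-quills the head
  nonquill <- purrr::map(seq_len(Z), function(k) {
    utils::head(zone_nodes[[k]], zone_sizes[k] - quill_counts[k])
  })
  quill <- purrr::map(seq_len(Z), function(k) {
    setdiff(zone_nodes[[k]], nonquill[[k]])
  })
  from <- rep("centre", zone_sizes[1])
  to <- zone_nodes[[1]]
  for (k in seq_len(Z)[-1]) {
    parents <- sample(nonquill[[k - 1]], zone_sizes[k], replace = TRUE)
    from <- c(from, parents)
    to <- c(to, zone_nodes[[k]])
  }
  for (k in seq_len(Z)) {
    nq <- nonquill[[k]]
    if (length(nq) >= 2 && intra_zone_density[k] > 0) {
      pairs <- which(upper.tri(matrix(0, length(nq), length(nq))), arr.ind = TRUE)
      pick <- runif(nrow(pairs)) < intra_zone_density[k]
      from <- c(from, nq[pairs[pick, 1]])
      to <- c(to, nq[pairs[pick, 2]])
    }
  }
  g <- interaction_graph(tibble(from = from, to = to))
  # fix-up: a non-quill node must not masquerade as a quill
  deg <- node_degrees(g)
  lonely <- deg$node[deg$degree == 1L & !(deg$node %in% unlist(quill)) & deg$node != "centre"]
  if (length(lonely) > 0) {
    extra_from <- character(0)
    extra_to <- character(0)
    for (v in lonely) {
      k <- as.integer(sub("^z(\\d+)_.*$", "\\1", v))
      nbrs <- c(g$edges$to[g$edges$from == v], g$edges$from[g$edges$to == v])
      cands <- if (k >= 2) setdiff(nonquill[[k - 1]], c(v, nbrs)) else character(0)
      if (length(cands) == 0) cands <- setdiff(nonquill[[k]], c(v, nbrs))
      if (length(cands) == 0) {
        abort("infeasible spec: cannot raise a non-quill node above degree 1")
      }
      extra_from <- c(extra_from, v)
      extra_to <- c(extra_to, sample_one(cands))
    }
    g <- interaction_graph(tibble(
      from = c(g$edges$from, extra_from),
      to = c(g$edges$to, extra_to)
    ))
  }
  truth <- tibble(
    node = c("centre", unlist(zone_nodes)),
    zone = c(0L, rep(seq_len(Z), zone_sizes)),
    is_quill = c(FALSE, unlist(purrr::map(seq_len(Z), function(k) {
      zone_nodes[[k]] %in% quill[[k]]
    })))
  )
  truth <- truth[order(truth$zone, truth$node), ]
  list(graph = g, centre = "centre", truth = truth)
}

# sample() with length-1 x means sample.int(x); avoid that trap
sample_one <- function(x) x[[sample.int(length(x), 1)]]

#' @export
print.planted_graph <- function(x, ...) {
  cat(sprintf(
    "<planted_graph> %d nodes, %d edges, %d zones around planted centre '%s' (%d attempt(s))\n",
    graph_order(x$graph), graph_size(x$graph), max(x$truth$zone), x$centre, x$attempts
  ))
  invisible(x)
}

#' Planted zone annotations for enrichment testing
#'
#' Builds a synthetic gene-set collection over the nodes of a zone map: one
#' designated set (`"planted_set"`) includes members of `planted_zone` with
#' probability `planted_density` and all other nodes with probability
#' `background_density`; the remaining sets sample every node at the
#' background rate. With equal densities the collection is a pure null. A set
#' that comes out empty receives one uniformly drawn node, since empty sets
#' are disallowed.
#'
#' @param zones A [zone_decompose()] result or any data frame with `node` and
#'   `zone` columns (e.g. the `truth` of [planted_core_periphery()]).
#' @param n_sets Total number of sets including the planted one (>= 1).
#' @param planted_zone Zone index carrying the signal.
#' @param planted_density,background_density Membership probabilities in
#'   \[0, 1\].
#' @param seed Optional integer seed.
#' @return A [gene_set_collection()]; the designated set is named
#'   `"planted_set"`.
#' @export
planted_annotations <- function(zones, n_sets = 20, planted_zone = 1,
                                planted_density = 0.4,
                                background_density = 0.05, seed = NULL) {
  if (!is.data.frame(zones) || !all(c("node", "zone") %in% names(zones))) {
    abort("`zones` must have `node` and `zone` columns")
  }
  if (n_sets < 1) abort("`n_sets` must be >= 1 (empty collections are disallowed)")
  densities <- c(planted_density, background_density)
  if (any(densities < 0 | densities > 1)) abort("densities must be in [0, 1]")
  nodes <- zones$node
  in_zone <- zones$zone == planted_zone
  draw <- function() {
    draw_set <- function(p) {
      s <- nodes[runif(length(nodes)) < p]
      if (length(s) == 0) s <- sample_one(nodes)
      s
    }
    planted <- nodes[runif(length(nodes)) < ifelse(in_zone, planted_density, background_density)]
    if (length(planted) == 0) planted <- sample_one(nodes)
    others <- purrr::map(seq_len(n_sets - 1), function(i) draw_set(background_density))
    sets <- c(list(planted_set = planted),
              rlang::set_names(others, sprintf("random_set_%02d", seq_along(others))))
    gene_set_collection(sets)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}
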