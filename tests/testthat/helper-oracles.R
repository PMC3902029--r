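# Independent oracles: brute-force / closed-form routes that never touch the
# package's BFS kernels.

# Floyd-Warshall all-pairs hop distances from the canonical edge tibble.
fw_distances <- function(g) {
  nodes <- graph_nodes(g)
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  e <- graph_edges(g)
  i <- match(e$from, nodes)
  j <- match(e$to, nodes)
  D[cbind(i, j)] <- 1
  D[cbind(j, i)] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

fw_eccentricities <- function(g) {
  D <- fw_distances(g)
  apply(D, 1, max)
}

# Union-find component count over an edge tibble.
uf_components <- function(g) {
  nodes <- graph_nodes(g)
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  e <- graph_edges(g)
  i <- match(e$from, nodes)
  j <- match(e$to, nodes)
  for (r in seq_along(i)) {
    ri <- find(i[r])
    rj <- find(j[r])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  membership <- match(roots, unique(roots))
  list(n_components = length(unique(roots)), membership = membership)
}

# Exact one-sided hypergeometric upper tail P[X >= k] by direct term summing.
hyper_tail_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  if (length(i) == 0 || min(K, n) < k) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Erdos-Renyi G(n, m) over letter-ish ids; resampled until connected
# (connectivity judged by the union-find oracle, not the package).
random_connected_graph <- function(n, m, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    repeat {
      all_pairs <- utils::combn(ids, 2)
      pick <- sample(ncol(all_pairs), min(m, ncol(all_pairs)))
      g <- interaction_graph(data.frame(t(all_pairs[, pick])))
      if (graph_order(g) == n && uf_components(g)$n_components == 1) {
        return(g)
      }
    }
  })
}

# Hand-checkable fixtures.
path_graph <- function(ids) {
  interaction_graph(data.frame(from = ids[-length(ids)], to = ids[-1]))
}

star_graph <- function(hub, leaves) {
  interaction_graph(data.frame(from = hub, to = leaves))
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(graph_edges(g), directed = FALSE,
                                vertices = graph_nodes(g))
}
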