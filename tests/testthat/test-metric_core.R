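test_that("components partition the node set with deterministic ordering", {
  g <- interaction_graph(data.frame(from = c("A", "C"), to = c("B", "D")))
  comps <- graph_components(g)
  expect_equal(comps$n_components, 2)
  # size tie broken by smallest node id: {A,B} is the giant
  expect_equal(comps$giant, c("A", "B"))

  p5 <- path_graph(letters[1:5])
  c5 <- graph_components(p5)
  expect_equal(c5$n_components, 1)
  expect_equal(length(c5$giant), 5)
})

test_that("component counts match union-find and igraph on random graphs", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      ids <- sprintf("n%03d", 1:200)
      e <- data.frame(
        from = sample(ids, 160, replace = TRUE),
        to = sample(ids, 160, replace = TRUE)
      )
    })
    g <- interaction_graph(e, nodes = sprintf("n%03d", 1:200))
    comps <- graph_components(g)
    expect_equal(comps$n_components, uf_components(g)$n_components)
    expect_equal(comps$n_components, igraph::count_components(as_igraph(g)))
    # membership partitions the node set
    expect_equal(sum(comps$sizes), graph_order(g))
    expect_setequal(comps$membership$node, graph_nodes(g))
  }
})

test_that("eccentricities on hand-checkable fixtures are exact", {
  p5 <- path_graph(c("a", "b", "c", "d", "e"))
  em <- node_eccentricities(p5)
  expect_equal(em$eccentricity[match(c("a", "b", "c", "d", "e"), em$node)],
               c(4L, 3L, 2L, 3L, 4L))
  expect_equal(attr(em, "radius"), 2L)
  expect_equal(attr(em, "diameter"), 4L)
  expect_equal(attr(em, "centre"), "c")

  s6 <- star_graph("hub", paste0("l", 1:5))
  em6 <- node_eccentricities(s6)
  expect_equal(attr(em6, "radius"), 1L)
  expect_equal(attr(em6, "diameter"), 2L)
  expect_equal(graph_centre(s6), "hub")

  disconnected <- interaction_graph(data.frame(from = c("A", "C"), to = c("B", "D")))
  expect_error(node_eccentricities(disconnected), "giant component")
})

test_that("eccentricity map matches the Floyd-Warshall oracle on a fixed-seed graph", {
  g <- random_connected_graph(30, 55, seed = 42)
  em <- node_eccentricities(g)
  oracle <- fw_eccentricities(g)
  expect_equal(em$eccentricity, unname(oracle[em$node]))
})

test_that("the centre contains every node attaining the radius", {
  p4 <- path_graph(c("a", "b", "c", "d"))
  expect_equal(graph_centre(p4), c("b", "c"))
  expect_equal(graph_centre(star_graph("hub", paste0("l", 1:5))), "hub")
})

test_that("zone decomposition layers by distance to the nearest centre node", {
  s6 <- star_graph("hub", paste0("l", 1:5))
  z <- zone_decompose(s6, centre = "hub")
  expect_equal(sum(z$zone == 1), 5)
  expect_equal(attr(z, "max_zone"), 1L)

  # multi-source layering on the even path
  p4 <- path_graph(c("a", "b", "c", "d"))
  z4 <- zone_decompose(p4, centre = c("b", "c"))
  expect_equal(sort(z4$node[z4$zone == 1]), c("a", "d"))
  expect_equal(attr(z4, "max_zone"), 1L)

  expect_error(zone_decompose(p4, centre = "zzz"), "absent")
})

test_that("zone indices agree with BFS distance and the planted ground truth", {
  pg <- planted_core_periphery(seed = 5)
  z <- zone_decompose(pg$graph, centre = pg$centre)
  truth <- pg$truth
  expect_equal(z$zone, truth$zone[match(z$node, truth$node)])
})

test_that("metric invariants hold on random connected instances", {
  for (seed in 1:10) {
    g <- random_connected_graph(25, 45, seed = 100 + seed)
    em <- node_eccentricities(g)
    r <- attr(em, "radius")
    d <- attr(em, "diameter")
    expect_lte(r, d)
    expect_lte(d, 2 * r)
    expect_gt(length(attr(em, "centre")), 0)
    z <- zone_decompose(g, centre = attr(em, "centre"))
    # zones partition the graph; counts add up
    expect_equal(nrow(z), graph_order(g))
    expect_equal(sum(z$zone == 0), length(attr(em, "centre")))
    # adjacent nodes' zone indices differ by at most 1, and every node in
    # zone k >= 1 has a neighbour in zone k - 1
    zmap <- rlang::set_names(z$zone, z$node)
    e <- graph_edges(g)
    expect_true(all(abs(zmap[e$from] - zmap[e$to]) <= 1))
    for (k in seq_len(attr(z, "max_zone"))) {
      members <- z$node[z$zone == k]
      has_parent <- vapply(members, function(v) {
        nb <- c(e$to[e$from == v], e$from[e$to == v])
        any(zmap[nb] == k - 1)
      }, logical(1))
      expect_true(all(has_parent))
    }
  }
})

test_that("eccentricities cross-check against igraph on a larger instance", {
  g <- random_connected_graph(60, 110, seed = 77)
  em <- node_eccentricities(g)
  ig_ecc <- igraph::eccentricity(as_igraph(g))
  expect_equal(em$eccentricity, unname(ig_ecc[em$node]))
})
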