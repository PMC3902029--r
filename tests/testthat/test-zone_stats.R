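test_that("zone degree summaries match hand-checkable fixtures", {
  s6 <- star_graph("hub", paste0("l", 1:5))
  z6 <- zone_decompose(s6, centre = "hub")
  s <- zone_summary(s6, z6)
  expect_equal(s$n_nodes, 5L)
  expect_equal(s$mean_degree, 1)
  expect_equal(s$min_degree, 1L)
  expect_equal(s$max_degree, 1L)
  expect_equal(s$n_quills, 5L)
  expect_equal(s$n_induced_components, 5L)

  p5 <- path_graph(c("a", "b", "c", "d", "e"))
  z5 <- zone_decompose(p5, centre = "c")
  s5 <- zone_summary(p5, z5)
  expect_equal(s5$zone, 1:2)
  expect_equal(s5$mean_degree, c(2, 1))
  expect_equal(s5$n_quills, c(0L, 2L))
})

test_that("per-zone quill counts equal the generator's planted counts", {
  pg <- planted_core_periphery(seed = 9)
  z <- zone_decompose(pg$graph, centre = pg$centre)
  s <- zone_summary(pg$graph, z)
  planted <- dplyr::count(
    dplyr::filter(pg$truth, zone >= 1), zone,
    wt = is_quill, name = "n_quills"
  )
  expect_equal(s$n_quills, as.integer(planted$n_quills))
  expect_equal(s$n_nodes, c(50L, 200L, 100L))
})

test_that("hub tally equals a full-sort oracle and the threshold rule caps it", {
  # hub with degree 19 over a background of degree ~5 nodes
  withr::with_seed(3, {
    leaves <- sprintf("l%02d", 1:19)
    extra <- t(utils::combn(leaves, 2))
    extra <- extra[sample(nrow(extra), 40), ]
  })
  g <- interaction_graph(data.frame(
    from = c(rep("hub", 19), extra[, 1]),
    to = c(leaves, extra[, 2])
  ))
  z <- zone_decompose(g, centre = graph_centre(g))
  h <- hub_distribution(g, z, fraction = 0.05)
  deg <- node_degrees(g)
  n <- nrow(deg)
  cap <- ceiling(0.05 * n)
  # oracle: scan every integer threshold for the smallest admitting <= cap
  counts <- vapply(0:(max(deg$degree) + 1), function(d) sum(deg$degree >= d), integer(1))
  d_star <- (0:(max(deg$degree) + 1))[which(counts <= cap)[1]]
  admitted <- deg$node[deg$degree >= d_star]
  expect_equal(attr(h, "total_top"), length(admitted))
  expect_lte(attr(h, "total_top"), cap)
  oracle_tally <- table(factor(z$zone[match(admitted, z$node)], levels = 0:attr(z, "max_zone")))
  expect_equal(h$n_top, as.integer(oracle_tally))
  expect_equal(sum(h$pct_top), 100, tolerance = 1e-9)
})

test_that("all-tied degrees admit nobody when the cap is below the tie size", {
  # 6-cycle: every node has degree 2; cap = ceil(0.3) = 2 < 6 tied nodes
  ids <- sprintf("c%d", 1:6)
  cyc <- interaction_graph(data.frame(from = ids, to = ids[c(2:6, 1)]))
  z <- zone_decompose(cyc, centre = graph_centre(cyc))
  h <- hub_distribution(cyc, z, fraction = 0.3)
  expect_equal(attr(h, "total_top"), 0L)
  expect_equal(h$pct_top, rep(0, nrow(h)))
})

test_that("hub exclusion removes nodes before thresholding and tallying", {
  pg <- planted_core_periphery(seed = 21)
  z <- zone_decompose(pg$graph, centre = pg$centre)
  top_nodes <- dplyr::arrange(node_degrees(pg$graph), dplyr::desc(degree))$node
  drop <- setdiff(utils::head(top_nodes, 3), pg$centre)
  h0 <- hub_distribution(pg$graph, z)
  h1 <- hub_distribution(pg$graph, z, exclude = drop)
  expect_equal(attr(h1, "n_excluded"), length(drop))
  expect_lte(attr(h1, "threshold_degree"), attr(h0, "threshold_degree"))
  expect_error(hub_distribution(pg$graph, z, fraction = 1.2), "fraction")
})

test_that("zone-degree correlation matches the explicit Pearson formula", {
  # exactly linear-decreasing means
  lin <- tibble::tibble(zone = 1:5, mean_degree = c(50, 40, 30, 20, 10))
  expect_equal(zone_degree_correlation(lin), -1)

  # constant means: undefined, NA with a warning
  flat <- tibble::tibble(zone = 1:4, mean_degree = rep(3, 4))
  expect_warning(r_flat <- zone_degree_correlation(flat), "constant")
  expect_true(is.na(r_flat))

  expect_error(zone_degree_correlation(tibble::tibble(zone = 1:2, mean_degree = c(2, 1))),
               "3 zones")

  # six-zone profile with a realistic steep core-periphery decay,
  # hand-computed through the raw sum formula
  y <- c(67, 24, 7, 2, 2, 3)
  x <- 1:6
  dx <- x - mean(x)
  dy <- y - mean(y)
  oracle <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  got <- zone_degree_correlation(tibble::tibble(zone = x, mean_degree = y))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, -0.8143271, tolerance = 1e-6)
  expect_lt(got, -0.7)
})

test_that("induced zone subgraphs inherit exactly the within-zone edges", {
  s6 <- star_graph("hub", paste0("l", 1:5))
  z6 <- zone_decompose(s6, centre = "hub")
  sub <- induced_zone_subgraph(s6, z6, 1)
  expect_equal(graph_order(sub), 5)
  expect_equal(graph_size(sub), 0)

  # K4 plus a pendant: zone 1 induces a triangle and an isolated node
  k4 <- t(utils::combn(c("a", "b", "c", "d"), 2))
  g <- interaction_graph(data.frame(
    from = c(k4[, 1], "a"),
    to = c(k4[, 2], "e")
  ))
  expect_equal(graph_centre(g), "a")
  z <- zone_decompose(g, centre = "a")
  sub1 <- induced_zone_subgraph(g, z, 1)
  expect_setequal(graph_nodes(sub1), c("b", "c", "d", "e"))
  expect_equal(graph_size(sub1), 3)
  comps <- graph_components(sub1)
  expect_equal(comps$n_components, 2)
  expect_error(induced_zone_subgraph(g, z, 5), "zone index")
})

test_that("planted graphs show the core-periphery gradient: dense core, quill fringe", {
  for (seed in c(2, 4)) {
    pg <- planted_core_periphery(seed = seed)
    z <- zone_decompose(pg$graph, centre = pg$centre)
    induced_mean <- vapply(1:3, function(k) {
      sub <- induced_zone_subgraph(pg$graph, z, k)
      2 * graph_size(sub) / graph_order(sub)
    }, numeric(1))
    expect_true(all(diff(induced_mean) < 0))
    # the outermost zone is pure quills: its induced subgraph has no edges
    fringe <- induced_zone_subgraph(pg$graph, z, 3)
    expect_equal(graph_size(fringe), 0)
    s <- zone_summary(pg$graph, z)
    expect_lt(zone_degree_correlation(s), -0.7)
  }
})
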