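test_that("GMT parsing: membership, dedup, errors, round-trip", {
  path <- withr::local_tempfile(lines = c(
    "S1\tdesc\tA\tB\tC",
    "S2\tdesc\tB\tB\tD"
  ))
  col <- read_gmt(path)
  expect_equal(col$sets$S1, c("A", "B", "C"))
  expect_equal(col$sets$S2, c("B", "D")) # duplicate member collapsed

  dup <- withr::local_tempfile(lines = c("S1\td\tA", "S1\td\tB"))
  expect_error(read_gmt(dup), "duplicate")
  short <- withr::local_tempfile(lines = c("S1\td\tA", "S2\tdesc_only"))
  expect_error(read_gmt(short), "line 2")

  out <- withr::local_tempfile()
  write_gmt(col, out)
  expect_equal(read_gmt(out)$sets, col$sets)

  expect_error(gene_set_collection(list()), "non-empty")
  expect_error(gene_set_collection(list(S1 = character())), "empty gene sets")
})

test_that("hypergeometric tail matches exhaustive enumeration to 1e-12 for N <= 60", {
  pg <- planted_core_periphery(c(10, 20), c(0.5, 0.1), c(0, 5), seed = 2)
  z <- zone_decompose(pg$graph, centre = pg$centre)
  universe <- z$node
  withr::with_seed(8, {
    sets <- purrr::map(1:8, ~ sample(universe, sample(3:25, 1)))
  })
  col <- gene_set_collection(rlang::set_names(sets, paste0("s", 1:8)))
  res <- zone_enrichment(z, col, universe = universe, quiet = TRUE)
  expect_lte(max(res$N), 60)
  oracle <- purrr::pmap_dbl(res[, c("k", "K", "N", "n")], function(k, K, N, n) {
    hyper_tail_oracle(k, K, N, n)
  })
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  # structural invariants of each test
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$proportion >= 0 & res$proportion <= 1, na.rm = TRUE))
})

test_that("degenerate overlaps give exact closed-form p-values", {
  # zone of 10 entirely inside a set of 10 within a universe of 100
  nodes <- sprintf("u%03d", 1:100)
  z <- tibble::tibble(
    node = nodes,
    zone = c(0L, rep(1L, 10), rep(2L, 89)),
    degree = 1L
  )
  z <- pinmetric:::new_zone_decomposition(z, centre = nodes[1])
  zone1 <- z$node[z$zone == 1]
  col <- gene_set_collection(list(hit = zone1, miss = z$node[z$zone == 2][1:10]))
  res <- zone_enrichment(z, col, universe = nodes, quiet = TRUE)
  hit1 <- res[res$zone == 1 & res$set_name == "hit", ]
  expect_equal(hit1$k, 10L)
  expect_equal(hit1$p_value, choose(10, 10) * choose(90, 0) / choose(100, 10),
               tolerance = 1e-12)
  # zero overlap: one-sided tail is exactly 1
  miss1 <- res[res$zone == 1 & res$set_name == "miss", ]
  expect_equal(miss1$k, 0L)
  expect_equal(miss1$p_value, 1)
})

test_that("a zone spanning the whole universe can never be enriched", {
  nodes <- sprintf("u%02d", 1:30)
  z <- tibble::tibble(node = nodes, zone = c(0L, rep(1L, 29)), degree = 1L)
  z <- pinmetric:::new_zone_decomposition(z, centre = nodes[1])
  col <- gene_set_collection(list(s1 = nodes[2:12], s2 = nodes[13:30]))
  res <- zone_enrichment(z, col, universe = nodes[-1], quiet = TRUE)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$k == res$K))
})

test_that("planted annotations recover the designated set as the zone's top hit", {
  recovered <- 0L
  n_seeds <- 25L
  pg <- planted_core_periphery(seed = 1)
  z <- zone_decompose(pg$graph, centre = pg$centre)
  props <- numeric(0)
  for (s in seq_len(n_seeds)) {
    col <- planted_annotations(pg$truth,
      n_sets = 20, planted_zone = 1,
      planted_density = 0.4, background_density = 0.05, seed = s
    )
    res <- zone_enrichment(z, col, universe = z$node, quiet = TRUE)
    z1 <- res[res$zone == 1, ]
    top <- z1[which.min(z1$p_adjusted), ]
    if (top$set_name == "planted_set" && top$significant) {
      recovered <- recovered + 1L
      props <- c(props, top$proportion)
    }
  }
  expect_gte(recovered / n_seeds, 0.95)
  # planted membership rate recovered within binomial error of 0.4
  expect_equal(mean(props), 0.4, tolerance = 3 * sqrt(0.4 * 0.6 / 50))
})

test_that("null collections are calibrated: few significant pairs at corrected 0.01", {
  pg <- planted_core_periphery(seed = 6)
  z <- zone_decompose(pg$graph, centre = pg$centre)
  n_sig <- 0L
  n_tests <- 0L
  for (s in 1:40) {
    col <- planted_annotations(pg$truth,
      n_sets = 10, planted_zone = 1,
      planted_density = 0.05, background_density = 0.05, seed = 1000 + s
    )
    res <- zone_enrichment(z, col, universe = z$node, quiet = TRUE)
    n_sig <- n_sig + sum(res$significant)
    n_tests <- n_tests + nrow(res)
  }
  expect_lte(n_sig / n_tests, 0.02)
})

test_that("specialisation table keeps top sets per zone and empty rows elsewhere", {
  pg <- planted_core_periphery(seed = 4)
  z <- zone_decompose(pg$graph, centre = pg$centre)
  col <- planted_annotations(pg$truth, seed = 12)
  res <- zone_enrichment(z, col, universe = z$node, quiet = TRUE)
  tab <- specialisation_table(res, top_n = 4)
  expect_true(all(sort(unique(tab$zone)) == sort(unique(res$zone))))
  z1 <- tab[tab$zone == 1, ]
  expect_equal(z1$set_name[1], "planted_set")
  expect_true(all(tab$pct >= 0 & tab$pct <= 100, na.rm = TRUE))
  # zones with no significant hit emit a single empty row
  empty_zones <- setdiff(unique(res$zone), unique(res$zone[res$significant]))
  for (ez in empty_zones) {
    expect_true(all(is.na(tab$set_name[tab$zone == ez])))
  }
  # a fully null result yields only empty rows
  null_res <- res
  null_res$significant <- FALSE
  tab0 <- specialisation_table(null_res)
  expect_true(all(is.na(tab0$set_name)))
})
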