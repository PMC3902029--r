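#' Per-zone degree summary (core-periphery table)
#'
#' For every zone k >= 1 around the centre: node count, mean/min/max degree,
#' quill count and the number of connected components of the induced zone
#' subgraph. Degrees are whole-graph degrees (a node adjacent only to the
#' centre has induced degree 0 but whole-graph degree 1 and counts as a
#' quill), which is the reading consistent with published per-zone tables. A
#' quill is a node of whole-graph degree exactly 1.
#'
#' @param g The connected [interaction_graph()] the zones were computed on
#'   (normally the giant component).
#' @param zones A [zone_decompose()] result for `g`.
#' @param eccentricities Optional [node_eccentricities()] result for `g`; if
#'   supplied, the graph-level diameter is recorded, otherwise it is `NA`.
#' @return A `zone_summary` tibble with one row per zone (`zone`, `n_nodes`,
#'   `mean_degree`, `min_degree`, `max_degree`, `n_quills`,
#'   `n_induced_components`) and graph-level attributes `graph_order`,
#'   `graph_size`, `diameter`, `centre`. Mean degrees are unrounded; round for
#'   display only.
#' @export
zone_summary <- function(g, zones, eccentricities = NULL) {
  stopifnot(inherits(g, "interaction_graph"), inherits(zones, "zone_decomposition"))
  check_zones_match(g, zones)
  max_zone <- attr(zones, "max_zone")
  rows <- purrr::map(seq_len(max_zone), function(k) {
    members <- zones$node[zones$zone == k]
    degs <- zones$degree[zones$zone == k]
    sub <- induced_subgraph_on(g, members)
    tibble(
      zone = k,
      n_nodes = length(members),
      mean_degree = mean(degs),
      min_degree = min(degs),
      max_degree = max(degs),
      n_quills = sum(degs == 1L),
      n_induced_components = graph_components(sub)$n_components
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    graph_order = graph_order(g),
    graph_size = graph_size(g),
    diameter = if (is.null(eccentricities)) NA_integer_ else attr(eccentricities, "diameter"),
    centre = attr(zones, "centre"),
    class = c("zone_summary", class(out))
  )
}

check_zones_match <- function(g, zones) {
  if (!setequal(zones$node, g$nodes)) {
    abort("`zones` does not cover exactly the nodes of `g`; compute zones on the same (giant-component) graph")
  }
  invisible(TRUE)
}

#' Placement of the top-degree hubs across zones
#'
#' Finds the smallest degree threshold `d` such that at most
#' `ceiling(fraction * n)` nodes have degree >= `d`, then tallies those hub
#' nodes per zone (zone 0 = the centre). The reported threshold is the
#' smallest *realised* degree with this property, which admits exactly the
#' same node set as scanning every integer. All nodes tied at the threshold
#' are admitted, so the realised hub count can be below the cap but never
#' above it. An optional exclusion set (e.g. a suspect dense complete subgraph) is
#' removed from the graph before degrees are computed, thresholded or
#' tallied.
#'
#' @inheritParams zone_summary
#' @param fraction Top fraction of the degree distribution to call hubs;
#'   default 0.05 (the top 5 percent), must be in (0, 1).
#' @param exclude Character vector of node identifiers to drop first.
#' @return A `hub_distribution` tibble with one row per zone 0..max_zone
#'   (`zone`, `n_nodes`, `n_top`, `pct_top`) and attributes
#'   `threshold_degree`, `total_top`, `fraction`, `n_excluded`. `pct_top` is
#'   the percentage of all hubs that fall in the zone (percentages sum to 100
#'   when any hub exists, and are 0 when the tie rule admits none).
#' @export
hub_distribution <- function(g, zones, fraction = 0.05, exclude = character()) {
  stopifnot(inherits(g, "interaction_graph"), inherits(zones, "zone_decomposition"))
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be a single number in (0, 1)")
  }
  check_zones_match(g, zones)
  exclude <- intersect(as.character(exclude), g$nodes)
  g2 <- if (length(exclude) > 0) exclude_nodes(g, exclude) else g
  deg <- node_degrees(g2)
  n <- nrow(deg)
  cap <- ceiling(fraction * n)
  # smallest d with |{deg >= d}| <= cap; counts are non-increasing in d
  candidates <- sort(unique(c(deg$degree, max(deg$degree) + 1L)))
  counts <- vapply(candidates, function(d) sum(deg$degree >= d), integer(1))
  threshold <- candidates[which(counts <= cap)[1]]
  hubs <- deg$node[deg$degree >= threshold]
  zone_tbl <- zones[!(zones$node %in% exclude), ]
  per_zone <- dplyr::count(
    dplyr::mutate(zone_tbl, is_top = .data$node %in% hubs),
    .data$zone,
    wt = .data$is_top, name = "n_top"
  )
  all_zones <- tibble(zone = 0:attr(zones, "max_zone"))
  out <- dplyr::left_join(all_zones, per_zone, by = "zone")
  out$n_top <- as.integer(dplyr::coalesce(out$n_top, 0L))
  sizes <- dplyr::count(zone_tbl, .data$zone, name = "n_nodes")
  out <- dplyr::left_join(out, sizes, by = "zone")
  out$n_nodes <- as.integer(dplyr::coalesce(out$n_nodes, 0L))
  total <- sum(out$n_top)
  out$pct_top <- if (total > 0) 100 * out$n_top / total else rep(0, nrow(out))
  out <- out[, c("zone", "n_nodes", "n_top", "pct_top")]
  structure(
    out,
    threshold_degree = threshold,
    total_top = total,
    fraction = fraction,
    n_excluded = length(exclude),
    class = c("hub_distribution", class(out))
  )
}

#' Correlation between zone index and mean degree
#'
#' Pearson correlation between the zone index (1..max) and the zone mean
#' degree — the summary statistic of the core-periphery gradient: strongly
#' negative values mean connectivity decays with distance from the centre.
#'
#' @param summary A [zone_summary()] result (or any data frame with `zone`
#'   and `mean_degree` columns) covering at least 3 zones.
#' @return A single correlation in `[-1, 1]`; `NA` with a warning when the
#'   mean degrees are constant (zero variance makes the coefficient
#'   undefined).
#' @export
zone_degree_correlation <- function(summary) {
  if (!is.data.frame(summary) || !all(c("zone", "mean_degree") %in% names(summary))) {
    abort("`summary` must have `zone` and `mean_degree` columns (see zone_summary())")
  }
  tbl <- summary[summary$zone >= 1, ]
  if (nrow(tbl) < 3) abort("zone-degree correlation needs at least 3 zones")
  if (stats::sd(tbl$mean_degree) == 0) {
    warn("mean degree is constant across zones; correlation is undefined")
    return(NA_real_)
  }
  cor(tbl$zone, tbl$mean_degree)
}

#' Induced subgraph of a single zone
#'
#' @inheritParams zone_summary
#' @param k Zone index, 1 <= k <= max zone.
#' @return The [interaction_graph()] induced on zone k's node set: all
#'   within-zone edges are inherited, cross-zone edges dropped.
#' @export
induced_zone_subgraph <- function(g, zones, k) {
  stopifnot(inherits(g, "interaction_graph"), inherits(zones, "zone_decomposition"))
  max_zone <- attr(zones, "max_zone")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > max_zone || k != round(k)) {
    abort(sprintf("`k` must be an integer zone index in 1..%d", max_zone))
  }
  induced_subgraph_on(g, zones$node[zones$zone == k])
}
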