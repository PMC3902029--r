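#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' zone summaries show node counts and mean degree against zone index, hub
#' distributions show the percentage of hubs per zone, and random
#' comparisons overlay per-zone node counts of reference and replicates.
#' [plot_degree_distribution()] shows the degree distribution of a graph on
#' log-log axes, where power-law-like networks appear roughly linear.
#'
#' @param object A pinmetric result.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pinmetric-plots
NULL

#' @rdname pinmetric-plots
#' @export
autoplot.zone_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object)[, c("zone", "n_nodes", "mean_degree", "n_quills")],
    -"zone",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$zone, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = unique(long$zone)) +
    ggplot2::labs(
      x = "zone (distance from centre)", y = NULL,
      title = "Core-periphery profile by zone"
    )
}

#' @rdname pinmetric-plots
#' @export
autoplot.hub_distribution <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$zone, y = .data$pct_top)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::scale_x_continuous(breaks = tbl$zone) +
    ggplot2::labs(
      x = "zone (0 = centre)", y = "% of hubs",
      title = sprintf(
        "Placement of top-degree hubs (degree >= %d, n = %d)",
        attr(object, "threshold_degree"), attr(object, "total_top")
      )
    )
}

#' @rdname pinmetric-plots
#' @export
autoplot.random_comparison <- function(object, ...) {
  zones <- object$zones
  zones$kind <- ifelse(zones$graph == zones$graph[1], "reference", "random replicate")
  ggplot2::ggplot(zones, ggplot2::aes(
    x = .data$zone, y = .data$n_nodes,
    group = .data$graph, colour = .data$kind
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(zones$zone)) +
    ggplot2::labs(
      x = "zone", y = "nodes in zone", colour = NULL,
      title = "Reference vs matched R-MAT random graphs"
    )
}

#' @rdname pinmetric-plots
#' @param g An [interaction_graph()].
#' @export
plot_degree_distribution <- function(g, ...) {
  deg <- node_degrees(g)
  counts <- dplyr::count(deg, .data$degree, name = "n_nodes")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$degree, y = .data$n_nodes)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree", y = "number of nodes",
      title = "Degree distribution (log-log)"
    )
}
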