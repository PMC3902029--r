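#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-node or per-row tibble of
#' a result, `glance()` a one-row summary.
#'
#' @param x A pinmetric result object.
#' @param ... Unused.
#' @return A tibble.
#' @name pinmetric-tidiers
NULL

#' @rdname pinmetric-tidiers
#' @export
tidy.eccentricity_map <- function(x, ...) {
  tibble(node = x$node, eccentricity = x$eccentricity)
}

#' @rdname pinmetric-tidiers
#' @export
glance.eccentricity_map <- function(x, ...) {
  tibble(
    n_nodes = nrow(x),
    radius = attr(x, "radius"),
    diameter = attr(x, "diameter"),
    n_centre = length(attr(x, "centre")),
    centre = paste(attr(x, "centre"), collapse = ",")
  )
}

#' @rdname pinmetric-tidiers
#' @export
tidy.component_decomposition <- function(x, ...) x$membership

#' @rdname pinmetric-tidiers
#' @export
glance.component_decomposition <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    giant_order = length(x$giant),
    giant_fraction = length(x$giant) / nrow(x$membership)
  )
}

#' @rdname pinmetric-tidiers
#' @export
tidy.zone_decomposition <- function(x, ...) {
  tibble(node = x$node, zone = x$zone, degree = x$degree)
}

#' @rdname pinmetric-tidiers
#' @export
glance.zone_decomposition <- function(x, ...) {
  tibble(
    n_nodes = nrow(x),
    n_centre = length(attr(x, "centre")),
    max_zone = attr(x, "max_zone"),
    centre = paste(attr(x, "centre"), collapse = ",")
  )
}

#' @rdname pinmetric-tidiers
#' @export
tidy.zone_summary <- function(x, ...) as_tibble(unclass_tbl(x))

#' @rdname pinmetric-tidiers
#' @export
glance.zone_summary <- function(x, ...) {
  tibble(
    graph_order = attr(x, "graph_order"),
    graph_size = attr(x, "graph_size"),
    diameter = attr(x, "diameter"),
    n_zones = nrow(x),
    centre = paste(attr(x, "centre"), collapse = ",")
  )
}

#' @rdname pinmetric-tidiers
#' @export
tidy.hub_distribution <- function(x, ...) as_tibble(unclass_tbl(x))

#' @rdname pinmetric-tidiers
#' @export
glance.hub_distribution <- function(x, ...) {
  tibble(
    threshold_degree = attr(x, "threshold_degree"),
    total_top = attr(x, "total_top"),
    fraction = attr(x, "fraction"),
    n_excluded = attr(x, "n_excluded")
  )
}

#' @rdname pinmetric-tidiers
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "alpha") <- NULL
  attr(out, "correction") <- NULL
  attr(out, "universe") <- NULL
  out
}

#' @rdname pinmetric-tidiers
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    correction = attr(x, "correction"),
    universe_size = length(attr(x, "universe"))
  )
}

#' @rdname pinmetric-tidiers
#' @export
tidy.random_comparison <- function(x, ...) x$zones

#' @rdname pinmetric-tidiers
#' @export
glance.random_comparison <- function(x, ...) x$graphs

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "graph_order") <- NULL
  attr(x, "graph_size") <- NULL
  attr(x, "diameter") <- NULL
  attr(x, "centre") <- NULL
  attr(x, "threshold_degree") <- NULL
  attr(x, "total_top") <- NULL
  attr(x, "fraction") <- NULL
  attr(x, "n_excluded") <- NULL
  x
}
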