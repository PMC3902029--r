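#' Run the full metric-space analysis of an interaction network
#'
#' End-to-end wrapper: load (or accept) a graph, extract the giant component,
#' compute exact eccentricities and the topological centre, decompose into
#' distance zones, and produce the per-zone degree summary, the hub
#' distribution and the zone-vs-mean-degree correlation. When `out_dir` is
#' given, results are written as diff-able TSV files with JSON twins
#' (`centre.txt`, `eccentricities.tsv`, `zones.tsv`, `summary.tsv`,
#' `hubs.tsv`, `summary.json`, `hubs.json`); every file carries a header
#' comment with the package version, a hash of the run configuration and the
#' seed, so runs are reproducible and attributable.
#'
#' @param edges An [interaction_graph()], or a path to an edge-list file.
#' @param out_dir Optional output directory (created if absent).
#' @param dialect Edge-list dialect when `edges` is a path; see
#'   [read_edge_list()].
#' @param top_fraction Hub fraction for [hub_distribution()]; default 0.05.
#' @param exclude Character vector of node identifiers to exclude from the
#'   hub analysis (e.g. a suspect dense complete subgraph), or a path to a
#'   one-id-per-line file.
#' @param seed Seed recorded in output headers (the analysis itself is
#'   deterministic).
#' @param quiet Suppress progress messages.
#' @return A `pin_analysis` list: `graph`, `components`, `giant`,
#'   `eccentricities`, `zones`, `summary`, `hubs`, `correlation` (`NA` when
#'   fewer than 3 zones), invisibly when `out_dir` is written.
#' @export
analyze_network <- function(edges, out_dir = NULL, dialect = "tsv",
                            top_fraction = 0.05, exclude = character(),
                            seed = NULL, quiet = FALSE) {
  g <- if (inherits(edges, "interaction_graph")) {
    edges
  } else {
    read_edge_list(edges, dialect = dialect, quiet = quiet)
  }
  if (length(exclude) == 1 && is.character(exclude) && file.exists(exclude)) {
    exclude <- readLines(exclude, warn = FALSE)
    exclude <- trimws(exclude[!grepl("^\\s*(#|$)", exclude)])
  }
  comps <- graph_components(g)
  if (!quiet) {
    inform(sprintf(
      "%d component(s); giant component holds %d of %d nodes (%.1f%%)",
      comps$n_components, length(comps$giant), graph_order(g),
      100 * length(comps$giant) / graph_order(g)
    ))
  }
  giant <- giant_component(g, comps)
  em <- node_eccentricities(giant)
  zones <- zone_decompose(giant, centre = attr(em, "centre"))
  summ <- zone_summary(giant, zones, eccentricities = em)
  hubs <- hub_distribution(giant, zones, fraction = top_fraction, exclude = exclude)
  correlation <- if (nrow(summ) >= 3) zone_degree_correlation(summ) else NA_real_
  res <- structure(
    list(
      graph = g, components = comps, giant = giant, eccentricities = em,
      zones = zones, summary = summ, hubs = hubs, correlation = correlation
    ),
    class = "pin_analysis"
  )
  if (is.null(out_dir)) return(res)
  write_analysis(res, out_dir, config = list(
    dialect = dialect, top_fraction = top_fraction,
    exclude = sort(as.character(exclude)), seed = seed
  ), seed = seed)
  invisible(res)
}

#' @export
print.pin_analysis <- function(x, ...) {
  cat(sprintf(
    "<pin_analysis> giant component: %d nodes / %d edges; centre {%s}; radius %d, diameter %d; %d zones; hub threshold %d; zone-degree correlation %s\n",
    graph_order(x$giant), graph_size(x$giant),
    paste(attr(x$eccentricities, "centre"), collapse = ", "),
    attr(x$eccentricities, "radius"), attr(x$eccentricities, "diameter"),
    attr(x$zones, "max_zone"), attr(x$hubs, "threshold_degree"),
    format(x$correlation, digits = 3)
  ))
  invisible(x)
}

output_header <- function(config, seed) {
  c(
    sprintf("pinmetric %s", as.character(utils::packageVersion("pinmetric"))),
    sprintf("config %s", rlang::hash(config)),
    sprintf("seed %s", seed %||% "none")
  )
}

write_tsv_with_header <- function(tbl, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines(paste(names(tbl), collapse = "\t"), con)
  if (nrow(tbl) > 0) {
    body <- do.call(paste, c(purrr::map(tbl, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

write_analysis <- function(res, out_dir, config, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(config, seed)
  writeLines(c(paste0("# ", hdr), attr(res$eccentricities, "centre")),
             file.path(out_dir, "centre.txt"))
  write_tsv_with_header(tidy(res$eccentricities),
                        file.path(out_dir, "eccentricities.tsv"), hdr)
  write_zone_table(res$zones, file.path(out_dir, "zones.tsv"), header = hdr)
  write_tsv_with_header(tidy(res$summary), file.path(out_dir, "summary.tsv"), hdr)
  write_tsv_with_header(tidy(res$hubs), file.path(out_dir, "hubs.tsv"), hdr)
  jsonlite::write_json(
    list(
      header = as.list(hdr),
      graph = as.list(glance(res$summary)),
      zones = tidy(res$summary),
      correlation = res$correlation
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  jsonlite::write_json(
    list(
      header = as.list(hdr),
      threshold = as.list(glance(res$hubs)),
      zones = tidy(res$hubs)
    ),
    file.path(out_dir, "hubs.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(out_dir)
}

#' Write a random-comparison report
#'
#' TSV + JSON twin of a [compare_to_random()] report, with the generator
#' parameters and seed in the header.
#'
#' @param report A `random_comparison`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_comparison <- function(report, out_dir) {
  stopifnot(inherits(report, "random_comparison"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    output_header(report$params, report$params$seed),
    sprintf(
      "rmat a=%s b=%s c=%s d=%s",
      report$params$a, report$params$b, report$params$c, report$params$d
    )
  )
  write_tsv_with_header(report$graphs, file.path(out_dir, "comparison_graphs.tsv"), hdr)
  write_tsv_with_header(report$zones, file.path(out_dir, "comparison_zones.tsv"), hdr)
  jsonlite::write_json(
    list(header = as.list(hdr), graphs = report$graphs, zones = report$zones),
    file.path(out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(out_dir)
}
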