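#' Gene-set collections (GMT)
#'
#' A collection is a named list of member-identifier sets plus an optional
#' analysis universe. [read_gmt()] parses the standard tab-separated GMT
#' format (set name, description, member ids); duplicate members within a
#' line are collapsed and the description column is ignored. Duplicate set
#' names make the collection ambiguous and are an error. [write_gmt()] writes
#' the same format back (description `"na"`), so write-then-read round-trips.
#'
#' @param sets Named list of character vectors (each non-empty).
#' @param universe Optional character vector of identifiers the tests
#'   condition on; usually left `NULL` and derived at test time.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!is.list(sets) || length(sets) == 0) abort("`sets` must be a non-empty named list")
  nm <- names(sets)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) abort("every gene set must be named")
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate gene-set name(s): %s", paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- purrr::map(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) abort("empty gene sets are not allowed")
  structure(
    list(sets = sets, universe = if (is.null(universe)) NULL else unique(as.character(universe))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d set(s), sizes %d..%d%s\n",
    length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
    if (is.null(x$universe)) "" else sprintf(", universe %d", length(x$universe))
  ))
  invisible(x)
}

#' @rdname gene_set_collection
#' @param path Path to a GMT file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) abort(sprintf("empty GMT file: %s", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields", idx[bad[1]]))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate gene-set name(s) in %s: %s", path,
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  gene_set_collection(rlang::set_names(purrr::map(fields, ~ .x[-(1:2)]), nm))
}

#' @rdname gene_set_collection
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- purrr::imap_chr(collection$sets, function(members, nm) {
    paste(c(nm, "na", members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Zone-wise hypergeometric over-representation analysis
#'
#' Tests every (zone, gene set) pair for over-representation with the
#' one-sided hypergeometric model: drawing `n` zone members from a universe
#' of `N` annotated nodes containing `K` set members, the p-value is
#' `P[X >= k]` for the observed overlap `k`. Only over-representation is
#' tested (depletion is not of interest here). P-values are corrected across
#' all pairs; pairs with corrected p at or below `alpha` are flagged
#' significant.
#'
#' The default universe is the set of giant-component nodes appearing in at
#' least one gene set, mirroring web enrichment services that condition on
#' annotated genes; set members outside the universe are trimmed before
#' counting (trimming is reported in a message). Zone 0 (the centre itself)
#' is not tested.
#'
#' @param zones A [zone_decompose()] result (its nodes define the giant
#'   component).
#' @param collection A [gene_set_collection()].
#' @param alpha Significance cutoff on the corrected p-value; default 0.01.
#' @param correction `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @param universe Optional explicit universe of node identifiers.
#' @param quiet Suppress the trimming/universe message.
#' @return An `enrichment_result` tibble sorted by `(zone, p_adjusted,
#'   set_name)` with columns `zone`, `set_name`, `k` (overlap), `K` (set size
#'   in universe), `n` (zone size in universe), `N` (universe size),
#'   `p_value`, `p_adjusted`, `proportion` (`k/n`; `NA` for zones with no
#'   annotated member) and `significant`. Attributes record `alpha`,
#'   `correction` and the universe.
#' @export
zone_enrichment <- function(zones, collection, alpha = 0.01,
                            correction = c("bh", "bonferroni"),
                            universe = NULL, quiet = FALSE) {
  stopifnot(inherits(zones, "zone_decomposition"), inherits(collection, "gene_set_collection"))
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1]")
  annotated <- unique(unlist(collection$sets, use.names = FALSE))
  universe <- universe %||% collection$universe %||% intersect(zones$node, annotated)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty universe: no zone node appears in any gene set")
  trimmed_sets <- purrr::map(collection$sets, intersect, universe)
  n_trimmed <- sum(lengths(collection$sets)) - sum(lengths(trimmed_sets))
  if (!quiet) {
    inform(sprintf(
      "universe: %d nodes; %d set member(s) outside the universe trimmed",
      length(universe), n_trimmed
    ))
  }
  N <- length(universe)
  zone_ids <- seq_len(attr(zones, "max_zone"))
  grid <- tidyr::expand_grid(zone = zone_ids, set_name = names(trimmed_sets))
  zone_members <- purrr::map(zone_ids, function(k) intersect(zones$node[zones$zone == k], universe))
  res <- purrr::pmap(grid, function(zone, set_name) {
    members <- zone_members[[zone]]
    set <- trimmed_sets[[set_name]]
    k <- length(intersect(members, set))
    n <- length(members)
    K <- length(set)
    tibble(
      zone = zone, set_name = set_name, k = k, K = K, n = n, N = N,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      proportion = if (n > 0) k / n else NA_real_
    )
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- p.adjust(out$p_value, method = if (correction == "bh") "BH" else "bonferroni")
  out$significant <- out$p_adjusted <= alpha
  out <- out[order(out$zone, out$p_adjusted, out$set_name), ]
  out <- out[, c("zone", "set_name", "k", "K", "n", "N", "p_value", "p_adjusted", "proportion", "significant")]
  structure(
    as_tibble(out),
    alpha = alpha, correction = correction, universe = universe,
    class = c("enrichment_result", class(as_tibble(out)))
  )
}

#' Zone specialisation table
#'
#' For each zone, reports the `top_n` significant gene sets (smallest
#' corrected p, ties broken by set name) together with the proportion of the
#' zone's annotated members they cover — high proportions in few sets mean
#' the zone is functionally specialised. Zones with no significant set keep a
#' single row with `NA` set name.
#'
#' @param results An [zone_enrichment()] result.
#' @param top_n Number of top sets per zone; default 4.
#' @return A tibble with columns `zone`, `rank`, `set_name`, `proportion`,
#'   `pct` (proportion as a percentage), `p_adjusted`.
#' @export
specialisation_table <- function(results, top_n = 4) {
  stopifnot(inherits(results, "enrichment_result"))
  if (nrow(results) == 0) abort("`results` is empty")
  if (top_n < 1) abort("`top_n` must be >= 1")
  sig <- results[results$significant, ]
  zones <- sort(unique(results$zone))
  rows <- purrr::map(zones, function(z) {
    hits <- sig[sig$zone == z, ]
    if (nrow(hits) == 0) {
      return(tibble(
        zone = z, rank = NA_integer_, set_name = NA_character_,
        proportion = NA_real_, pct = NA_real_, p_adjusted = NA_real_
      ))
    }
    hits <- hits[order(hits$p_adjusted, hits$set_name), ]
    hits <- utils::head(hits, top_n)
    tibble(
      zone = z, rank = seq_len(nrow(hits)), set_name = hits$set_name,
      proportion = hits$proportion, pct = 100 * hits$proportion,
      p_adjusted = hits$p_adjusted
    )
  })
  dplyr::bind_rows(rows)
}
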