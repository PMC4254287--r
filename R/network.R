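#' Build the weighted species co-occurrence network
#'
#' Species are nodes; an undirected edge of weight `w_ij` joins species i and
#' j if they co-occurred in at least `min_weight` clusters. Isolated species
#' are retained as nodes. The analysis default keeps every positive weight
#' (`min_weight = 1`); a threshold of 2 matches the display convention used
#' for the study's network figures.
#'
#' @param records A `cluster_records` data frame.
#' @param species_subset Optional species ids to retain (e.g. from
#'   [filter_by_detectability()]).
#' @param min_weight Minimum co-occurrence count for an edge.
#' @return A list of class `species_network` with elements `graph` (an
#'   igraph object whose edges carry a `weight` attribute), `species`, and
#'   `counts` (the full `co_occurrence_counts` matrix).
#' @export
build_network <- function(records, species_subset = NULL, min_weight = 1) {
  mat <- build_occurrence_matrix(records, species_subset = species_subset)
  network_from_counts(co_occurrence_counts(mat), min_weight = min_weight)
}

#' Build a species network directly from co-occurrence counts
#'
#' @param counts A `co_occurrence_counts` matrix.
#' @param min_weight Minimum co-occurrence count for an edge.
#' @return A `species_network` (see [build_network()]).
#' @export
network_from_counts <- function(counts, min_weight = 1) {
  stopifnot(inherits(counts, "co_occurrence_counts"))
  w <- unclass(counts)
  keep <- w
  keep[w < min_weight] <- 0L
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  structure(list(graph = g, species = rownames(w), counts = counts,
                 min_weight = min_weight),
            class = "species_network")
}

#' @export
print.species_network <- function(x, ...) {
  cat(sprintf("Species co-occurrence network: %d nodes, %d edges (min weight %d)\n",
              length(x$species), igraph::ecount(x$graph), x$min_weight))
  invisible(x)
}

#' Weighted betweenness of the species network
#'
#' Shortest-path betweenness with edge length `1/w_ij`, so a strongly
#' associated pair is a short hop: the more often two species co-occur, the
#' more readily paths (information, pathogens) flow along that edge.
#' Equal-length shortest paths split counts equally; unreachable pairs
#' contribute nothing; scores are unnormalized. With `binary = TRUE` all
#' edges get unit length instead (topology-only fallback).
#'
#' @param network A `species_network`.
#' @param binary Ignore weights and use unit edge lengths.
#' @return Named numeric vector of betweenness scores (one per node,
#'   isolated nodes score 0).
#' @export
betweenness_scores <- function(network, binary = FALSE) {
  stopifnot(inherits(network, "species_network"))
  g <- network$graph
  if (igraph::ecount(g) == 0) {
    return(setNames(numeric(length(network$species)), network$species))
  }
  weights <- if (binary) rep(1, igraph::ecount(g)) else
    1 / igraph::E(g)$weight
  b <- igraph::betweenness(g, directed = FALSE, weights = weights)
  b[network$species]
}

#' Betweenness ranks
#'
#' Converts betweenness scores to descending ranks (1 = highest score), with
#' tied scores receiving their average rank. Ranks rather than raw scores
#' are the comparison currency across ecosystems, seasons and simulation
#' replicates.
#'
#' @param scores Named numeric vector from [betweenness_scores()].
#' @return Named numeric vector of ranks.
#' @export
betweenness_ranks <- function(scores) {
  stopifnot(is.numeric(scores))
  rank(-scores, ties.method = "average")
}

#' Export the network edge list as CSV
#'
#' @param network A `species_network`.
#' @param path Output CSV path; columns `from`, `to`, `weight`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "species_network"))
  el <- igraph::as_edgelist(network$graph)
  df <- data.frame(from = el[, 1], to = el[, 2],
                   weight = if (igraph::ecount(network$graph) > 0)
                     igraph::E(network$graph)$weight else numeric(0),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export the network in Graphviz DOT format
#'
#' Plain undirected DOT export (node per species, edge per retained pair,
#' weight as an edge attribute) suitable for spring-model layout in
#' Graphviz; no layout is computed here.
#'
#' @param network A `species_network`.
#' @param path Output `.dot` path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(network, path) {
  stopifnot(inherits(network, "species_network"))
  el <- igraph::as_edgelist(network$graph)
  lines <- c("graph species_network {",
             paste0("  \"", network$species, "\";"))
  if (nrow(el) > 0) {
    wts <- igraph::E(network$graph)$weight
    lines <- c(lines,
               sprintf("  \"%s\" -- \"%s\" [weight=%g, len=%g];",
                       el[, 1], el[, 2], wts, 1 / wts))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
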