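#' Build the binarized alter-alter graph of a personal network
#'
#' One node per alter, one undirected edge per present (binarized) tie; the
#' ego is excluded by construction. Node ordering is deterministic (sorted
#' `alter_id`).
#'
#' @param network A `personal_network` object.
#' @return An undirected simple `igraph` graph whose vertex names are
#'   `alter_id`s.
#' @export
build_alter_graph <- function(network) {
  ids <- sort(network$alters$alter_id)
  ties <- network$ties
  present <- binarize_tie(ties$strength) == 1L
  el <- as.matrix(ties[present, c("a", "b"), drop = FALSE])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                            name = setdiff(ids, igraph::V(g)$name))
  igraph::permute(g, match(igraph::V(g)$name, ids))
}

# degree of each alter in the binarized graph, in alters-table row order
alter_degrees <- function(network) {
  g <- build_alter_graph(network)
  deg <- igraph::degree(g)
  unname(deg[network$alters$alter_id])
}

#' Density of an alter graph
#'
#' Proportion of present ties out of the theoretical number of ties,
#' `m / (n(n-1)/2)`.
#'
#' @param graph An `igraph` graph (from [build_alter_graph()]).
#' @return Ratio in `[0, 1]`.
#' @export
graph_density <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) {
    abort("degenerate input: density undefined for fewer than 2 alters")
  }
  igraph::ecount(graph) / choose(n, 2)
}

#' Number of connected components of an alter graph
#'
#' Counts the maximal connected pieces of the binarized alter graph; isolated
#' alters are stand-alone components. The alter graph is undirected, so
#' strong and weak components coincide.
#'
#' @param graph An `igraph` graph.
#' @return Integer component count (0 for the empty graph).
#' @export
component_count <- function(graph) {
  if (igraph::vcount(graph) == 0) return(0L)
  igraph::components(graph)$no
}

#' Normalized betweenness centrality of every alter
#'
#' Freeman shortest-path betweenness on the binarized, possibly disconnected
#' alter graph: for node v, the sum over unordered pairs of other nodes of the
#' fraction of geodesics through v, divided by the maximum possible
#' `(n-1)(n-2)/2` so scores are comparable across network sizes. Unreachable
#' pairs contribute 0; every score is 0 when the graph has at most 2 nodes.
#'
#' @param graph An `igraph` graph.
#' @return Named numeric vector (names are `alter_id`s), scores in `[0, 1]`.
#' @export
normalized_betweenness <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) return(setNames(numeric(0), character(0)))
  b <- igraph::betweenness(graph, directed = FALSE)
  if (n <= 2) return(setNames(rep(0, n), igraph::V(graph)$name))
  setNames(as.numeric(b) / choose(n - 1, 2), igraph::V(graph)$name)
}

#' Structural summary of every personal network in a study
#'
#' Computes the network-level measures (size, density, components) per ego and
#' normalized betweenness per alter, on the full binarized alter graph (before
#' any eligibility filtering).
#'
#' @param study A [study_data] object.
#' @return List of two tibbles: `networks` (`ego_id`, `size`, `density`,
#'   `components`) and `alters` (`ego_id`, `alter_id`, `betweenness`).
#' @export
structural_summary <- function(study) {
  nets <- networks(study)
  per_net <- vector("list", length(nets))
  per_alter <- vector("list", length(nets))
  for (i in seq_along(nets)) {
    net <- nets[[i]]
    g <- build_alter_graph(net)
    n <- igraph::vcount(g)
    per_net[[i]] <- tibble::tibble(
      ego_id = net$ego$ego_id, size = n,
      density = if (n >= 2) graph_density(g) else NA_real_,
      components = component_count(g))
    bw <- normalized_betweenness(g)
    per_alter[[i]] <- tibble::tibble(ego_id = net$ego$ego_id,
                                     alter_id = names(bw),
                                     betweenness = as.numeric(bw))
  }
  list(networks = dplyr::bind_rows(per_net),
       alters = dplyr::bind_rows(per_alter))
}
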