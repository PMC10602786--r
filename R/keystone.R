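#' Raw node centralities of a consortium network
#'
#' Topology uses absolute edge weights (signs matter for interpretation,
#' not for paths). Degree is node strength (sum of absolute incident
#' weights); path lengths use distance `1 / |weight|`; closeness is
#' harmonic closeness (sum of reciprocal shortest-path distances, an
#' unreachable node contributing 0), so disconnected networks and isolated
#' nodes are well defined; betweenness is weighted shortest-path
#' betweenness. Isolated nodes score (0, 0, 0).
#'
#' @param net a [consortium_network].
#' @param degree_mode `"strength"` (default, weighted) or `"count"` (number
#'   of incident edges).
#' @return Data frame: `taxon`, `betweenness_raw`, `closeness_raw`,
#'   `degree_raw`.
#' @export
centralities <- function(net, degree_mode = c("strength", "count")) {
  stopifnot(inherits(net, "consortium_network"))
  degree_mode <- match.arg(degree_mode)
  g <- as_igraph(net)
  nn <- length(net$nodes)
  if (nn == 0)
    return(data.frame(taxon = character(), betweenness_raw = numeric(),
                      closeness_raw = numeric(), degree_raw = numeric()))
  if (igraph::ecount(g) > 0) {
    dist_w <- 1 / abs(igraph::E(g)$weight)
    btw <- igraph::betweenness(g, weights = dist_w, directed = FALSE)
    clo <- igraph::harmonic_centrality(g, weights = dist_w,
                                       normalized = FALSE)
    deg <- if (degree_mode == "strength")
      igraph::strength(g, weights = abs(igraph::E(g)$weight))
    else igraph::degree(g)
  } else {
    btw <- clo <- deg <- setNames(rep(0, nn), net$nodes)
  }
  data.frame(taxon = net$nodes,
             betweenness_raw = as.numeric(btw[net$nodes]),
             closeness_raw = as.numeric(clo[net$nodes]),
             degree_raw = as.numeric(deg[net$nodes]),
             stringsAsFactors = FALSE)
}

#' Homogenize a centrality index across nodes
#'
#' Sum-to-one normalization: each raw index is divided by its total over
#' all nodes, putting betweenness, closeness and degree on one unitless
#' scale before they are mixed into the key-score. An all-zero index maps
#' to all zeros.
#'
#' @param raw non-negative numeric vector of raw centralities.
#' @return Normalized vector summing to 1 (or all zeros).
#' @export
homogenize <- function(raw) {
  if (any(raw < 0)) stop("raw centralities must be >= 0", call. = FALSE)
  s <- sum(raw)
  if (s > 0) raw / s else raw * 0
}

#' Keystone key-score
#'
#' `degree + closeness - betweenness` on homogenized centralities: high for
#' well-connected, central, non-bottleneck nodes, the profile expected of
#' keystone taxa (high degree and closeness, low betweenness).
#'
#' @param betweenness,closeness,degree homogenized centralities
#'   (vectorized).
#' @return The key-score.
#' @export
key_score <- function(betweenness, closeness, degree) {
  degree + closeness - betweenness
}

#' Per-node key-score table for a network
#'
#' Raw centralities, homogenized versions, and the key-score, one row per
#' node.
#'
#' @param net a [consortium_network].
#' @param degree_mode passed to [centralities()].
#' @return Data frame of class `key_score_table`.
#' @export
key_score_table <- function(net, degree_mode = "strength") {
  raw <- centralities(net, degree_mode = degree_mode)
  raw$betweenness <- homogenize(raw$betweenness_raw)
  raw$closeness <- homogenize(raw$closeness_raw)
  raw$degree <- homogenize(raw$degree_raw)
  raw$key_score <- key_score(raw$betweenness, raw$closeness, raw$degree)
  class(raw) <- c("key_score_table", "data.frame")
  raw
}

#' Rank taxa by key-score
#'
#' Descending key-score; ties broken by higher homogenized degree, then
#' lexicographic taxon identifier (a stable, documented order).
#'
#' @param table a [key_score_table()] result.
#' @return The taxa in rank order (best first).
#' @export
rank_keystones <- function(table) {
  ord <- order(-table$key_score, -table$degree, table$taxon)
  table$taxon[ord]
}
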