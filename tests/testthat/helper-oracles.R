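# Independent oracles and small fixtures shared across tests.

# Tiny relative-mode table from a raw matrix (closes rows).
toy_table <- function(m, generation = NULL) {
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  if (is.null(generation)) generation <- rep("G1", nrow(m))
  to_relative(abundance_table(m, generation, mode = "counts"))
}

# Hand-formula Bray-Curtis.
oracle_bray <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# Mutual information by direct contingency-table summation, using the same
# mid-rank equal-frequency binning contract.
oracle_mi <- function(x, y, bins) {
  bin_of <- function(v) pmin(pmax(floor((rank(v) - 0.5) * bins /
                                          length(v)), 0), bins - 1)
  tab <- table(factor(bin_of(x), levels = 0:(bins - 1)),
               factor(bin_of(y), levels = 0:(bins - 1))) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  s <- 0
  for (a in seq_len(bins)) for (b in seq_len(bins))
    if (tab[a, b] > 0) s <- s + tab[a, b] * log(tab[a, b] / (px[a] * py[b]))
  as.numeric(s)
}

# Exhaustive all-pairs shortest-path betweenness for small weighted graphs.
# edges: data.frame(a, b, w) with distances 1/w; nodes: ids.
oracle_betweenness <- function(nodes, edges) {
  nn <- length(nodes)
  btw <- setNames(rep(0, nn), nodes)
  path_len <- function(p) {
    if (length(p) < 2) return(0)
    s <- 0
    for (i in seq_len(length(p) - 1)) {
      hit <- which((edges$a == p[i] & edges$b == p[i + 1]) |
                     (edges$b == p[i] & edges$a == p[i + 1]))
      s <- s + 1 / edges$w[hit[1]]
    }
    s
  }
  simple_paths <- function(from, to) {
    res <- list()
    walk <- function(cur, path) {
      if (cur == to) { res[[length(res) + 1]] <<- path; return() }
      nbrs <- c(edges$b[edges$a == cur], edges$a[edges$b == cur])
      for (nb in setdiff(nbrs, path)) walk(nb, c(path, nb))
    }
    walk(from, from)
    res
  }
  for (si in seq_len(nn - 1)) for (ti in (si + 1):nn) {
    s <- nodes[si]; t <- nodes[ti]
    paths <- simple_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, path_len, numeric(1))
    dmin <- min(lens)
    short <- paths[abs(lens - dmin) < 1e-12]
    for (v in nodes) {
      if (v == s || v == t) next
      through <- sum(vapply(short, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / length(short)
    }
  }
  btw
}

# Harmonic closeness oracle via the same exhaustive shortest paths.
oracle_harmonic <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = nodes)
  d <- igraph::distances(g, weights = 1 / edges$w)
  diag(d) <- Inf
  rowSums(1 / d)[nodes]
}
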