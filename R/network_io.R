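#' Construct a signed weighted consortium network
#'
#' An undirected graph over taxa. Each edge carries a sign (`"+"` or `"-"`),
#' a positive combined association weight, and a merged BH q-value. Isolated
#' taxa are legitimate nodes (a taxon can be present yet unconnected in a
#' given generation).
#'
#' @param nodes character vector of taxon identifiers.
#' @param edges data frame with columns `taxon_a`, `taxon_b`, `sign`,
#'   `weight`, `q` (may have zero rows).
#' @return An object of class `consortium_network`.
#' @export
consortium_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers", call. = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(taxon_a = character(), taxon_b = character(),
                        sign = character(), weight = numeric(),
                        q = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(taxon_a = as.character(edges$taxon_a),
                        taxon_b = as.character(edges$taxon_b),
                        sign = as.character(edges$sign),
                        weight = as.numeric(edges$weight),
                        q = as.numeric(edges$q),
                        stringsAsFactors = FALSE)
    if (any(edges$taxon_a == edges$taxon_b))
      stop("self-edges are not allowed", call. = FALSE)
    if (!all(c(edges$taxon_a, edges$taxon_b) %in% nodes))
      stop("edge endpoint not in node set", call. = FALSE)
    if (!all(edges$sign %in% c("+", "-")))
      stop("edge sign must be '+' or '-'", call. = FALSE)
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("edge weights must be positive", call. = FALSE)
    key <- ifelse(edges$taxon_a < edges$taxon_b,
                  paste(edges$taxon_a, edges$taxon_b),
                  paste(edges$taxon_b, edges$taxon_a))
    if (anyDuplicated(key))
      stop("at most one edge per taxon pair", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "consortium_network")
}

#' @export
print.consortium_network <- function(x, ...) {
  cat(sprintf("consortium_network: %d nodes, %d edges (%d +, %d -)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

#' Convert a consortium network to an igraph graph
#'
#' Edge attribute `weight` is the absolute association weight; `sign` and
#' `q` are carried along. Topological analyses ignore signs.
#'
#' @param net a [consortium_network].
#' @return An undirected `igraph` graph with all nodes retained.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "consortium_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(match(net$edges$taxon_a, net$nodes),
               match(net$edges$taxon_b, net$nodes)),
      weight = net$edges$weight, sign = net$edges$sign, q = net$edges$q)
  }
  g
}

#' Write a consortium network to disk
#'
#' `edgelist` is a 5-column TSV (`taxon_a`, `taxon_b`, `sign`, `weight`,
#' `q`) preceded by one `#nodes` comment line declaring the full node set
#' (so isolated nodes survive a round trip). `graphml` is standard GraphML
#' with `sign`, `weight`, `q` edge attributes, importable in Gephi or
#' Cytoscape. Numeric attributes are written at full double precision.
#'
#' @param net a [consortium_network].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(net, "consortium_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#nodes\t", paste(net$nodes, collapse = "\t")), con)
    writeLines("taxon_a\ttaxon_b\tsign\tweight\tq", con)
    if (nrow(net$edges) > 0) {
      writeLines(sprintf("%s\t%s\t%s\t%.17g\t%.17g",
                         net$edges$taxon_a, net$edges$taxon_b,
                         net$edges$sign, net$edges$weight, net$edges$q), con)
    }
  } else {
    xml_escape <- function(s)
      gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", s)))
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="d0" for="edge" attr.name="sign" attr.type="string"/>',
      '  <key id="d1" for="edge" attr.name="weight" attr.type="double"/>',
      '  <key id="d2" for="edge" attr.name="q" attr.type="double"/>',
      '  <graph id="G" edgedefault="undirected">',
      sprintf('    <node id="%s"/>', xml_escape(net$nodes)))
    if (nrow(net$edges) > 0) {
      lines <- c(lines, sprintf(
        paste0('    <edge source="%s" target="%s">',
               '<data key="d0">%s</data>',
               '<data key="d1">%.17g</data>',
               '<data key="d2">%.17g</data></edge>'),
        xml_escape(net$edges$taxon_a), xml_escape(net$edges$taxon_b),
        net$edges$sign, net$edges$weight, net$edges$q))
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a consortium network written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edgelist"`; guessed from the extension
#'   when missing.
#' @return A [consortium_network].
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path)) "graphml" else "edgelist"
  }
  format <- match.arg(format, c("graphml", "edgelist"))
  if (format == "edgelist") {
    first <- readLines(path, n = 1L)
    if (!startsWith(first, "#nodes"))
      stop("edge list missing #nodes header line", call. = FALSE)
    nodes <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
    df <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                     stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "character",
                                    "numeric", "numeric"))
    consortium_network(nodes, df)
  } else {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    keys <- xml2::xml_find_all(doc, ".//g:key", ns)
    key_name <- setNames(xml2::xml_attr(keys, "attr.name"),
                         xml2::xml_attr(keys, "id"))
    nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
    edge_nodes <- xml2::xml_find_all(doc, ".//g:edge", ns)
    if (length(edge_nodes) > 0) {
      get_attr <- function(e, name) {
        dat <- xml2::xml_find_all(e, "./g:data", ns)
        ids <- xml2::xml_attr(dat, "key")
        hit <- which(key_name[ids] == name)
        if (length(hit) == 0) NA_character_ else xml2::xml_text(dat[[hit[1]]])
      }
      df <- data.frame(
        taxon_a = xml2::xml_attr(edge_nodes, "source"),
        taxon_b = xml2::xml_attr(edge_nodes, "target"),
        sign = vapply(edge_nodes, get_attr, character(1), name = "sign"),
        weight = as.numeric(
          vapply(edge_nodes, get_attr, character(1), name = "weight")),
        q = as.numeric(
          vapply(edge_nodes, get_attr, character(1), name = "q")),
        stringsAsFactors = FALSE)
    } else df <- NULL
    consortium_network(nodes, df)
  }
}
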