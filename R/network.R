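# Weighted co-participation network construction. Every multinational study
# contributes one connection per unordered pair of its countries; the weight
# of an edge is the number of studies its two countries shared.

#' Extract the unordered country pairs of one multinational study
#'
#' A study carried out in k countries yields all C(k, 2) unordered pairs,
#' each stored in canonical (lexicographic) order so that (a, b) and (b, a)
#' denote the same connection.
#'
#' @param countries Character vector of at least two distinct countries.
#' @return Data frame with columns `u`, `v` (`u < v`), one row per pair.
#' @examples
#' extract_pairs(c("1", "2", "3"))
#' @export
extract_pairs <- function(countries) {
  countries <- unique(as.character(countries))
  if (length(countries) < 2L) {
    stop("pair extraction requires a multinational study (>= 2 countries)")
  }
  cs <- sort(countries)
  cmb <- utils::combn(cs, 2L)
  data.frame(u = cmb[1L, ], v = cmb[2L, ], stringsAsFactors = FALSE)
}

#' Build the master list of connections
#'
#' Concatenates the extracted pairs of every multinational study into a
#' single multiset of connection instances: one row per (study, pair)
#' incidence. Its size is the sum of C(k_s, 2) over studies s, and it is
#' independent of study order up to row permutation.
#'
#' @param registry A [trial_registry()] containing only multinational
#'   studies (see [filter_multinational()]); anything else is an error.
#' @return Data frame with columns `u`, `v`, sorted canonically.
#' @export
build_master_list <- function(registry) {
  stopifnot(inherits(registry, "trial_registry"))
  if (nrow(registry) == 0L) {
    return(data.frame(u = character(0), v = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(lengths(registry$countries) < 2L)) {
    stop("master list requires studies filtered to multinational; ",
         "call filter_multinational() first")
  }
  us <- vector("list", nrow(registry))
  vs <- vector("list", nrow(registry))
  for (i in seq_len(nrow(registry))) {
    cs <- sort(unique(registry$countries[[i]]))
    cmb <- utils::combn(cs, 2L)
    us[[i]] <- cmb[1L, ]
    vs[[i]] <- cmb[2L, ]
  }
  out <- data.frame(u = unlist(us, use.names = FALSE),
                    v = unlist(vs, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse a master list into weighted edges
#'
#' Each distinct pair becomes one edge whose weight is the pair's
#' multiplicity in the master list, i.e. the number of studies both
#' countries participated in. Weights sum to the master-list size.
#'
#' @param master Data frame with columns `u`, `v` as returned by
#'   [build_master_list()].
#' @return Data frame with columns `u`, `v`, `weight` (positive integers),
#'   sorted by `u` then `v`.
#' @export
weight_edges <- function(master) {
  stopifnot(is.data.frame(master), all(c("u", "v") %in% names(master)))
  if (nrow(master) == 0L) {
    return(data.frame(u = character(0), v = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(master$u, master$v, sep = "\x1f")
  tab <- table(key)
  parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
  out <- data.frame(u = vapply(parts, `[`, "", 1L),
                    v = vapply(parts, `[`, "", 2L),
                    weight = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the integrated trial network
#'
#' Runs pair extraction, master-list accumulation, and edge weighting, and
#' computes each country's node size: the weighted total of its incident
#' connections (the sum of weights of its edges), which reflects the number
#' of multinational studies the country is involved in. The degree-sum
#' identity holds by construction: sum of node sizes = 2 x total edge weight.
#'
#' @param registry A [trial_registry()] of multinational studies.
#' @return Object of class `trial_network`: a list with elements `nodes`
#'   (data frame `country`, `size`), `edges` (data frame `u`, `v`, `weight`)
#'   and `n_studies`.
#' @examples
#' reg <- trial_registry(c("A", "B"), c(2000L, 2001L),
#'                       list(c("1", "2", "3"), c("2", "3", "4")))
#' build_network(reg)
#' @export
build_network <- function(registry) {
  edges <- weight_edges(build_master_list(registry))
  if (nrow(edges) == 0L) {
    nodes <- data.frame(country = character(0), size = integer(0),
                        stringsAsFactors = FALSE)
  } else {
    sz <- tapply(rep(edges$weight, 2L), c(edges$u, edges$v), sum)
    nodes <- data.frame(country = names(sz), size = as.integer(sz),
                        stringsAsFactors = FALSE)
    nodes <- nodes[order(nodes$country), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, n_studies = nrow(registry)),
            class = "trial_network")
}

#' @export
print.trial_network <- function(x, ...) {
  cat("<trial_network> ", nrow(x$nodes), " countries, ", nrow(x$edges),
      " edges, total weight ", sum(x$edges$weight),
      " (from ", x$n_studies, " multinational studies)\n", sep = "")
  invisible(x)
}

#' Write a network edge list as CSV
#'
#' Columns `source`, `target`, `weight`; rows in canonical order so repeated
#' runs produce byte-identical files.
#'
#' @param net A `trial_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "trial_network"))
  df <- data.frame(source = net$edges$u, target = net$edges$v,
                   weight = net$edges$weight, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.node_regions <- function(net, region_map, strict = FALSE) {
  if (is.null(region_map)) {
    return(rep(NA_character_, nrow(net$nodes)))
  }
  assign_region(net$nodes$country, region_map, strict = strict)
}

#' Export a network as GraphML
#'
#' Nodes carry attributes `size` (weighted connection total) and `region`;
#' edges carry `weight`. The file loads directly into Gephi or igraph.
#'
#' @param net A `trial_network`.
#' @param path Output path.
#' @param region_map Optional country -> region map for the node attribute.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, region_map = NULL) {
  stopifnot(inherits(net, "trial_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("u", "v", "weight")], directed = FALSE,
    vertices = net$nodes[, c("country", "size")])
  igraph::V(g)$region <- .node_regions(net, region_map)[
    match(igraph::V(g)$name, net$nodes$country)]
  if (is.null(region_map)) g <- igraph::delete_vertex_attr(g, "region")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network as GEXF
#'
#' Writes GEXF 1.2 (the native Gephi format): undirected weighted edges,
#' node attributes `size` and `region`.
#'
#' @inheritParams write_network_graphml
#' @return `path`, invisibly.
#' @export
write_network_gexf <- function(net, path, region_map = NULL) {
  stopifnot(inherits(net, "trial_network"))
  regions <- .node_regions(net, region_map)
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                               mode = "static")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "size",
                      type = "double")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "region",
                      type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = net$nodes$country[i],
                              label = net$nodes$country[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = as.character(net$nodes$size[i]))
    if (!is.na(regions[i])) {
      xml2::xml_add_child(av, "attvalue", "for" = "1", value = regions[i])
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(net$edges))) {
    xml2::xml_add_child(edges, "edge",
                        id = as.character(i - 1L),
                        source = net$edges$u[i],
                        target = net$edges$v[i],
                        weight = as.character(net$edges$weight[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
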