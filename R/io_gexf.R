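#' Correlation-network export
#'
#' Networks built by [build_network()] are exported as GEXF 1.2 (the
#' format Gephi reads; the study's networks were laid out there) together
#' with a plain edge-list TSV for toolchain-independent re-reading.
#'
#' @name io_gexf
NULL

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export a correlation network as GEXF (plus an edge-list TSV)
#'
#' Nodes carry `kind` (taxon / parameter / function) and `degree`
#' attributes; edges carry `rho`, `sign` and `p`. An empty network
#' produces a valid file with zero edges. The edge list is written next
#' to the GEXF file as `<path>.edges.tsv` (or at `edge_path`).
#'
#' @param network a `correlation_network` from [build_network()].
#' @param path output GEXF path.
#' @param edge_path output path for the edge-list TSV.
#' @return `path`, invisibly.
#' @export
export_network_gexf <- function(network, path,
                                edge_path = paste0(path, ".edges.tsv")) {
  stopifnot(inherits(network, "correlation_network"))
  nodes <- network$nodes
  edges <- network$edges
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph mode="static" defaultedgetype="undirected">')
  w('    <attributes class="node">')
  w('      <attribute id="kind" title="kind" type="string"/>')
  w('      <attribute id="degree" title="degree" type="integer"/>')
  w('    </attributes>')
  w('    <attributes class="edge">')
  w('      <attribute id="rho" title="rho" type="double"/>')
  w('      <attribute id="sign" title="sign" type="integer"/>')
  w('      <attribute id="p" title="p" type="double"/>')
  w('    </attributes>')
  w('    <nodes>')
  for (i in seq_len(nrow(nodes))) {
    w('      <node id="%s" label="%s">', xml_escape(nodes$id[i]),
      xml_escape(nodes$id[i]))
    w('        <attvalues>')
    w('          <attvalue for="kind" value="%s"/>', xml_escape(nodes$kind[i]))
    w('          <attvalue for="degree" value="%d"/>', nodes$degree[i])
    w('        </attvalues>')
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  for (i in seq_len(nrow(edges))) {
    w('      <edge id="e%d" source="%s" target="%s" weight="%.12g">',
      i, xml_escape(edges$u[i]), xml_escape(edges$v[i]), abs(edges$rho[i]))
    w('        <attvalues>')
    w('          <attvalue for="rho" value="%.12g"/>', edges$rho[i])
    w('          <attvalue for="sign" value="%d"/>', edges$sign[i])
    w('          <attvalue for="p" value="%.12g"/>', edges$p[i])
    w('        </attvalues>')
    w('      </edge>')
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  write_edge_list(network, edge_path)
  invisible(path)
}

#' @rdname export_network_gexf
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "correlation_network"))
  edges <- network$edges
  edges$rho <- signif(edges$rho, 12)
  edges$p <- signif(edges$p, 12)
  write_tsv(edges[c("u", "v", "rho", "sign", "p")], path)
  nodes <- network$nodes
  write_tsv(nodes[c("id", "kind", "degree")],
            sub("\\.tsv$", ".nodes.tsv", path))
  invisible(path)
}

#' Rebuild a correlation network from its edge-list TSV
#'
#' @param path edge-list TSV written by [write_edge_list()].
#' @return a `correlation_network`.
#' @export
read_edge_list <- function(path) {
  edges <- read_tsv_checked(path, c("u", "v", "rho", "sign", "p"), "edge list")
  node_path <- sub("\\.tsv$", ".nodes.tsv", path)
  if (file.exists(node_path)) {
    nodes <- read_tsv_checked(node_path, c("id", "kind", "degree"), "node list")
  } else {
    ids <- unique(c(edges$u, edges$v))
    nodes <- data.frame(id = ids, kind = NA_character_,
                        degree = vapply(ids, function(i)
                          sum(edges$u == i | edges$v == i), integer(1)),
                        stringsAsFactors = FALSE)
  }
  if (nrow(edges) == 0L)
    edges <- data.frame(u = character(0), v = character(0),
                        rho = numeric(0), sign = integer(0), p = numeric(0))
  structure(list(nodes = nodes, edges = edges, alpha = NA_real_),
            class = "correlation_network")
}
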