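# Network export. All writers emit nodes and edges in lexicographic order
# so outputs are diffable across runs.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export an overlap network
#'
#' Writes an [build_overlap_network()] result as GraphML (node attribute
#' `mirna_count`, edge attribute `weight`), SIF (relation `overlaps`), or a
#' plain edge list (`edge-tsv`: columns `a`, `b`, `weight`, with weights at
#' 12 significant digits so a re-import reproduces the edge set and
#' weights). GraphML/SIF files load directly into Cytoscape; layout is up
#' to the viewer.
#'
#' @param network An `overlap_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "sif", "edge-tsv")) {
  stopifnot(inherits(network, "overlap_network"))
  if (length(format) == 1L && !format %in% c("graphml", "sif", "edge-tsv")) {
    stop_stratmir(sprintf("unknown graph format '%s'", format))
  }
  format <- match.arg(format)
  nodes <- dplyr::arrange(network$nodes, .data$pathway)
  edges <- dplyr::arrange(network$edges, .data$a, .data$b)
  lines <- switch(
    format,
    "graphml" = {
      c('<?xml version="1.0" encoding="UTF-8"?>',
        '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
        '  <key id="d0" for="node" attr.name="mirna_count" attr.type="int"/>',
        '  <key id="d1" for="edge" attr.name="weight" attr.type="double"/>',
        '  <graph id="G" edgedefault="undirected">',
        sprintf('    <node id="%s"><data key="d0">%d</data></node>',
                xml_escape(nodes$pathway), as.integer(nodes$mirna_count)),
        if (nrow(edges) > 0L) {
          sprintf('    <edge source="%s" target="%s"><data key="d1">%s</data></edge>',
                  xml_escape(edges$a), xml_escape(edges$b),
                  formatC(edges$weight, digits = 12, format = "g"))
        },
        '  </graph>',
        '</graphml>')
    },
    "sif" = {
      isolated <- setdiff(nodes$pathway, c(edges$a, edges$b))
      c(if (nrow(edges) > 0L) paste(edges$a, "overlaps", edges$b, sep = "\t"),
        isolated)
    },
    "edge-tsv" = {
      c("a\tb\tweight",
        if (nrow(edges) > 0L) {
          paste(edges$a, edges$b,
                formatC(edges$weight, digits = 12, format = "g"), sep = "\t")
        })
    })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an edge-TSV network file
#'
#' Re-imports a file written by [export_graph()] with `format = "edge-tsv"`.
#' Node attributes are not stored in this format; the returned network's
#' nodes carry `mirna_count = NA`.
#'
#' @param path Path to the edge-TSV file.
#' @return An `overlap_network` with the edge set and weights of the file.
#' @export
read_edge_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("a", "b", "weight") %in% names(df))) {
    stop_stratmir("edge-tsv needs columns a, b, weight")
  }
  nodes <- tibble(pathway = sort(unique(c(df$a, df$b))),
                  mirna_count = NA_integer_)
  structure(list(nodes = nodes,
                 edges = dplyr::arrange(as_tibble(df), .data$a, .data$b)),
            class = "overlap_network")
}
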