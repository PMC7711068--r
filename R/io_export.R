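# Deterministic file exports (edge list, node list, adjacency matrix,
# GraphML) and the edge+node-list reader that reconstructs a network.

.write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(file)
}

#' Export a network to a file
#'
#' Output is deterministic: nodes are ordered by chain, sequence position,
#' insertion code and atom role; edges are oriented and sorted in that node
#' order. GraphML (written via igraph) carries node and edge attributes,
#' including weights.
#'
#' @param net An `aan`.
#' @param file Output path.
#' @param format One of `"edgelist_tsv"`, `"nodelist_tsv"`,
#'   `"adjacency_tsv"`, `"graphml"`.
#' @return The output path, invisibly.
#' @export
export_network <- function(net, file,
                           format = c("edgelist_tsv", "nodelist_tsv",
                                      "adjacency_tsv", "graphml")) {
  stopifnot(inherits(net, "aan"))
  format <- match.arg(format)
  dir <- dirname(file)
  if (!dir.exists(dir)) {
    stop("I/O error: directory does not exist: ", dir)
  }
  if (format == "edgelist_tsv") {
    ed <- net$edges[, c("node_i", "node_j", "weight", "energy", "distance",
                        "long_range"), drop = FALSE]
    .write_tsv(ed, file)
  } else if (format == "nodelist_tsv") {
    cols <- c("node_id", "label", "chain", "resno", "icode", "node_kind",
              "ss")
    if (!is.null(net$nodes$weight)) cols <- c(cols, "weight")
    .write_tsv(net$nodes[, cols, drop = FALSE], file)
  } else if (format == "adjacency_tsv") {
    am <- as.data.frame(net$AM)
    am <- cbind(node_id = rownames(net$AM), am)
    .write_tsv(am, file)
  } else {
    g <- as_igraph(net)
    # igraph refuses NA attributes in GraphML; blank them out
    for (a in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, a)
      if (is.character(v)) igraph::vertex_attr(g, a) <- ifelse(is.na(v), "", v)
    }
    for (a in igraph::edge_attr_names(g)) {
      v <- igraph::edge_attr(g, a)
      if (is.numeric(v) && anyNA(v)) {
        igraph::edge_attr(g, a) <- ifelse(is.na(v), 0, v)
      }
    }
    igraph::write_graph(g, file, format = "graphml")
  }
  invisible(file)
}

#' Reconstruct a network from exported edge and node lists
#'
#' Inverse of the `edgelist_tsv` + `nodelist_tsv` exports: rebuilds the node
#' table, edge table and adjacency matrix.
#'
#' @param edge_file,node_file Paths written by [export_network()].
#' @param model_type The network model type of the export.
#' @return An `aan`.
#' @export
read_network <- function(edge_file, node_file,
                         model_type = c("AACEN", "NACEN", "EACEN",
                                        "CALPHA")) {
  model_type <- match.arg(model_type)
  nodes <- utils::read.table(node_file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             colClasses = NA, na.strings = "NA")
  nodes$icode[is.na(nodes$icode)] <- ""
  nodes$chain <- as.character(nodes$chain)
  edges <- utils::read.table(edge_file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             na.strings = "NA")
  if (nrow(edges) > 0) {
    edges$i <- match(edges$node_i, nodes$node_id)
    edges$j <- match(edges$node_j, nodes$node_id)
    if (anyNA(edges$i) || anyNA(edges$j)) {
      stop("edge list references node id(s) absent from the node list")
    }
  } else {
    edges$i <- integer(0)
    edges$j <- integer(0)
  }
  ed <- data.frame(i = edges$i, j = edges$j,
                   energy = as.numeric(edges$energy),
                   distance = as.numeric(edges$distance),
                   weight = as.numeric(edges$weight),
                   long_range = as.logical(edges$long_range))
  .make_aan(model_type, nodes, ed, params = list(imported = TRUE))
}
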