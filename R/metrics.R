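# Node-, edge- and network-level topological metrics. Production metrics are
# computed with igraph; conventions (normalisation, disconnected handling,
# length transforms) are fixed here and recorded in output metadata.

#' Convert an aan to an igraph graph
#'
#' @param x An `aan`.
#' @return Undirected igraph graph whose vertices carry the node table
#'   columns and whose edges carry `weight` (model edge weight), `energy`,
#'   `distance` and `long_range`.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "aan"))
  g <- igraph::graph_from_data_frame(
    d = x$edges[, setdiff(names(x$edges), c("i", "j")), drop = FALSE],
    directed = FALSE,
    vertices = x$nodes)
  g
}

# Path lengths used for shortest-path metrics: EACEN edge weights are
# coupling strengths, so strong links are short (length 1/w); unweighted
# models use length 1. Returns NULL for "no weights" (igraph convention).
.path_lengths <- function(x, eacen_length = c("inverse", "direct")) {
  eacen_length <- match.arg(eacen_length)
  if (x$model_type == "EACEN" && nrow(x$edges) > 0) {
    if (eacen_length == "inverse") 1 / x$edges$weight else x$edges$weight
  } else {
    NULL
  }
}

# closeness = reachable/(sum of distances) and mean distance per node, from
# a full distance matrix; isolated nodes get closeness 0, mean distance NA
.closeness_from_dist <- function(d) {
  diag(d) <- NA
  reach <- rowSums(is.finite(d), na.rm = TRUE)
  total <- rowSums(ifelse(is.finite(d), d, 0), na.rm = TRUE)
  closeness <- ifelse(reach > 0 & total > 0, reach / total, 0)
  avg <- ifelse(reach > 0, total / reach, NA_real_)
  list(closeness = closeness, avg = avg)
}

#' Node-level topological metrics
#'
#' Per node: degree (edge count), shortest-path betweenness (unnormalised),
#' closeness (number of reachable nodes divided by the sum of their
#' shortest-path distances, computed over reachable nodes only), local
#' clustering coefficient (`transitivity`; 0 for degree < 2), and the mean
#' shortest-path distance to all reachable nodes. For EACEN networks
#' shortest paths use edge length 1/w (strong couplings are short);
#' transitivity and degree remain topological.
#'
#' @param net An `aan`.
#' @param eacen_length EACEN length transform: `"inverse"` (1/w, default) or
#'   `"direct"` (w).
#' @return Data frame with one row per node.
#' @export
node_metrics <- function(net, eacen_length = "inverse") {
  stopifnot(inherits(net, "aan"))
  if (nrow(net$nodes) == 0) stop("empty network")
  g <- as_igraph(net)
  len <- .path_lengths(net, eacen_length)
  d <- igraph::distances(g, weights = len)
  cl <- .closeness_from_dist(d)
  out <- data.frame(
    node_id = net$nodes$node_id,
    degree = unname(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, weights = len,
                                             normalized = FALSE)),
    closeness = unname(cl$closeness),
    transitivity = unname(igraph::transitivity(g, type = "localundirected",
                                               isolates = "zero")),
    avg_shortest_path = unname(cl$avg),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Node-weighted centralities for NACEN networks
#'
#' Weighted degree of node i is the sum of the weights of its neighbours.
#' Weighted betweenness and closeness are shortest-path centralities on the
#' edge-length transform l_ij = (w_i + w_j) / 2, so paths through light
#' (e.g. low-polarity) residues are short. With uniform weights the weighted
#' centralities reproduce the unweighted rankings. Weighted closeness is the
#' standard key for ranking putative functional/allosteric residues.
#'
#' @param net An `aan` with node weights (NACEN).
#' @return Data frame with `node_id`, `weighted_degree`,
#'   `weighted_betweenness`, `weighted_closeness`.
#' @export
node_weighted_metrics <- function(net) {
  stopifnot(inherits(net, "aan"))
  w <- net$nodes$weight
  if (is.null(w)) stop("network has no node weights; build it with ",
                       "build_nacen()")
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("contract violation: node-weighted path metrics require positive ",
         "finite node weights (found min ", format(min(w)), "); rescale or ",
         "choose another weight mode")
  }
  g <- as_igraph(net)
  i <- match(net$edges$node_i, net$nodes$node_id)
  j <- match(net$edges$node_j, net$nodes$node_id)
  len <- (w[i] + w[j]) / 2
  if (nrow(net$edges) == 0) len <- NULL
  am <- net$AM != 0
  wdeg <- as.vector(am %*% w)
  d <- igraph::distances(g, weights = len)
  cl <- .closeness_from_dist(d)
  data.frame(
    node_id = net$nodes$node_id,
    weighted_degree = wdeg,
    weighted_betweenness = unname(igraph::betweenness(g, weights = len,
                                                      normalized = FALSE)),
    weighted_closeness = unname(cl$closeness),
    stringsAsFactors = FALSE)
}

#' Edge-level metrics
#'
#' Shortest-path edge betweenness (unnormalised) per edge, plus the
#' long-range label: an edge is long-range when its endpoints lie in
#' different chains (or molecules), or are amino-acid nodes of the same
#' chain separated by at least `lr_sep` in sequence.
#'
#' @param net An `aan`.
#' @param lr_sep Sequence-separation threshold for the long-range label.
#' @param eacen_length EACEN length transform (see [node_metrics()]).
#' @return Data frame with `node_i`, `node_j`, `edge_betweenness`,
#'   `long_range`.
#' @export
edge_metrics <- function(net, lr_sep = 12, eacen_length = "inverse") {
  stopifnot(inherits(net, "aan"))
  if (nrow(net$nodes) == 0) stop("empty network")
  g <- as_igraph(net)
  len <- .path_lengths(net, eacen_length)
  eb <- if (nrow(net$edges) > 0) {
    unname(igraph::edge_betweenness(g, weights = len, directed = FALSE))
  } else {
    numeric(0)
  }
  idx <- data.frame(i = match(net$edges$node_i, net$nodes$node_id),
                    j = match(net$edges$node_j, net$nodes$node_id))
  data.frame(node_i = net$edges$node_i, node_j = net$edges$node_j,
             edge_betweenness = eb,
             long_range = .label_long_range(net$nodes, idx, lr_sep),
             stringsAsFactors = FALSE)
}

#' Network-level metrics
#'
#' Node count n, edge count m, mean shortest-path length L_net over
#' connected node pairs, density 2m/(n(n-1)) and diameter (largest finite
#' eccentricity). Disconnected networks are handled component-wise: L_net
#' and the diameter consider reachable pairs only. A network without edges
#' has L_net = NA and diameter 0.
#'
#' @param net An `aan`.
#' @param eacen_length EACEN length transform (see [node_metrics()]).
#' @return One-row data frame `(n, m, L_net, density, diameter)`.
#' @export
network_metrics <- function(net, eacen_length = "inverse") {
  stopifnot(inherits(net, "aan"))
  n <- nrow(net$nodes)
  m <- nrow(net$edges)
  g <- as_igraph(net)
  len <- .path_lengths(net, eacen_length)
  d <- igraph::distances(g, weights = len)
  vals <- d[upper.tri(d)]
  finite <- vals[is.finite(vals)]
  l_net <- if (length(finite) > 0 && m > 0) mean(finite) else NA_real_
  diam <- if (length(finite) > 0 && m > 0) max(finite) else 0
  density <- if (n > 1) 2 * m / (n * (n - 1)) else 0
  data.frame(n = n, m = m, L_net = l_net, density = density,
             diameter = diam)
}

#' Full metrics report for one network
#'
#' Bundles [node_metrics()] (plus [node_weighted_metrics()] for NACEN),
#' [edge_metrics()] and [network_metrics()], with the conventions used
#' recorded in the `conventions` field.
#'
#' @param net An `aan`.
#' @param lr_sep Long-range sequence-separation threshold.
#' @param eacen_length EACEN length transform (see [node_metrics()]).
#' @return An object of class `metrics_report`: list with `node_table`,
#'   `edge_table`, `network_row`, `conventions`.
#' @export
metrics_report <- function(net, lr_sep = 12, eacen_length = "inverse") {
  nt <- node_metrics(net, eacen_length)
  conventions <- c(
    betweenness = "unnormalised shortest-path betweenness",
    closeness = "reachable-count / sum-of-distances (component-wise)",
    eacen_length = if (net$model_type == "EACEN")
      paste0("path length = ",
             if (eacen_length == "inverse") "1/w (strong links short)" else
               "w") else "unweighted",
    long_range = paste0("|delta seq| >= ", lr_sep,
                        " within a chain, or inter-chain"))
  if (net$model_type == "NACEN") {
    wt <- node_weighted_metrics(net)
    nt <- merge(nt, wt, by = "node_id", sort = FALSE)
    conventions <- c(conventions,
                     weighted_length = "l_ij = (w_i + w_j)/2")
  }
  structure(list(node_table = nt,
                 edge_table = edge_metrics(net, lr_sep, eacen_length),
                 network_row = network_metrics(net, eacen_length),
                 conventions = conventions),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report\n")
  cat("network:\n")
  print(x$network_row, row.names = FALSE)
  cat("node table: ", nrow(x$node_table), " rows; edge table: ",
      nrow(x$edge_table), " rows\n", sep = "")
  invisible(x)
}
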