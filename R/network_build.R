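# The four amino-acid network models. All builders return an `aan` object:
# node table, edge table and symmetric adjacency matrix, tagged by model type.

.aan_types <- c("AACEN", "NACEN", "EACEN", "CALPHA")

# assemble an aan from a node table and an edge index table; nodes are put
# in canonical order (chain, seq position, insertion code, atom role) and
# edges oriented/sorted accordingly, so all outputs are deterministic
.make_aan <- function(model_type, nodes, edges, params, provenance = NULL,
                      log = character()) {
  kind_rank <- match(nodes$node_kind, c("amino_acid", "P", "C4*", "C2"))
  ord <- order(nodes$chain, nodes$resno, nodes$icode, kind_rank,
               method = "radix")
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  if (nrow(edges) > 0) {
    edges$i <- remap[edges$i]
    edges$j <- remap[edges$j]
    flip <- edges$i > edges$j
    tmp <- edges$i[flip]
    edges$i[flip] <- edges$j[flip]
    edges$j[flip] <- tmp
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    if (anyDuplicated(edges[, c("i", "j")])) {
      stop("internal error: duplicate edges")
    }
  }
  n <- nrow(nodes)
  am <- matrix(0, n, n, dimnames = list(nodes$node_id, nodes$node_id))
  if (nrow(edges) > 0) {
    stopifnot(!any(edges$i == edges$j))
    am[cbind(edges$i, edges$j)] <- edges$weight
    am[cbind(edges$j, edges$i)] <- edges$weight
    edges$node_i <- nodes$node_id[edges$i]
    edges$node_j <- nodes$node_id[edges$j]
  } else {
    edges$node_i <- character(0)
    edges$node_j <- character(0)
  }
  first <- c("node_i", "node_j")
  edges <- edges[, c(first, setdiff(names(edges), first)), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(model_type = model_type, nodes = nodes, edges = edges,
                 AM = am, params = params, provenance = provenance,
                 log = log),
            class = "aan")
}

# long-range rule: different chains/molecules, or same-chain amino-acid
# pairs at least lr_sep apart in sequence
.label_long_range <- function(nodes, edges, lr_sep) {
  if (nrow(edges) == 0) return(logical(0))
  ci <- nodes$chain[edges$i]; cj <- nodes$chain[edges$j]
  ki <- nodes$node_kind[edges$i]; kj <- nodes$node_kind[edges$j]
  sep <- abs(nodes$resno[edges$i] - nodes$resno[edges$j])
  (ci != cj) |
    (ki == "amino_acid" & kj == "amino_acid" & ci == cj & sep >= lr_sep)
}

.aa_node_table <- function(s) {
  aa <- s$residues[s$residues$kind == "amino_acid", , drop = FALSE]
  data.frame(node_id = aa$node_id, label = aa$resname, chain = aa$chain,
             resno = aa$resno, icode = aa$icode,
             node_kind = rep("amino_acid", nrow(aa)),
             ss = aa$ss, stringsAsFactors = FALSE)
}

# shared AACEN/NACEN/EACEN edge rule: candidate contact AND e_ij < e_thresh
.energy_edges <- function(s, table, e_thresh, d_cutoff, exclude_adjacent,
                          atom_mode) {
  aa <- s$residues[s$residues$kind == "amino_acid", , drop = FALSE]
  if (nrow(aa) == 0) {
    stop("empty-network error: structure has no amino-acid residues")
  }
  if (any(is.na(aa$ss))) {
    stop("secondary structure not assigned; run ",
         "assign_secondary_structure() first")
  }
  cand <- candidate_contacts(s, d_cutoff = d_cutoff,
                             exclude_adjacent = exclude_adjacent,
                             atom_mode = atom_mode)
  lab <- .energy_label(aa$resname, aa$ss)
  e <- unname(table[cbind(lab[cand$i], lab[cand$j])])
  keep <- e < e_thresh
  data.frame(i = cand$i[keep], j = cand$j[keep],
             energy = e[keep], distance = cand$distance[keep])
}

#' Build an amino acid contact energy network (AACEN)
#'
#' Nodes are the amino-acid residues; an undirected edge joins two residues
#' when they are a geometric candidate contact and their environment-dependent
#' contact energy e_ij is below the threshold (strictly: e_ij = threshold
#' gives no edge). The adjacency matrix is binary.
#'
#' @param s A `structure_model`; secondary structure is assigned on the fly
#'   if missing.
#' @param table An `energy_table`.
#' @param e_thresh Energy threshold; default 0 (edge iff e_ij < 0).
#' @param d_cutoff Candidate-contact distance cutoff in Angstrom.
#' @param exclude_adjacent Same-chain sequence-separation exclusion (pairs
#'   with |delta seq| < this value are never edges).
#' @param atom_mode Contact geometry, `"calpha"` or `"heavy"`.
#' @param lr_sep Sequence separation labelling an edge long-range.
#' @return An `aan` with `model_type = "AACEN"`.
#' @export
build_aacen <- function(s, table = load_energy_table(), e_thresh = 0,
                        d_cutoff = 8.0, exclude_adjacent = 2,
                        atom_mode = "calpha", lr_sep = 12) {
  stopifnot(inherits(s, "structure_model"), inherits(table, "energy_table"))
  if (any(is.na(s$residues$ss[s$residues$kind == "amino_acid"]))) {
    s <- assign_secondary_structure(s)
  }
  ed <- .energy_edges(s, table, e_thresh, d_cutoff, exclude_adjacent,
                      atom_mode)
  nodes <- .aa_node_table(s)
  ed$weight <- rep(1, nrow(ed))
  ed$long_range <- .label_long_range(nodes, ed, lr_sep)
  .make_aan("AACEN", nodes, ed,
            params = list(e_thresh = e_thresh, d_cutoff = d_cutoff,
                          exclude_adjacent = exclude_adjacent,
                          atom_mode = atom_mode, lr_sep = lr_sep),
            provenance = attr(table, "provenance"))
}

#' Build a node-weighted amino acid contact energy network (NACEN)
#'
#' The edge set is identical to [build_aacen()] on the same inputs; in
#' addition every node carries a weight: relative solvent accessibility,
#' mass, hydrophobicity, polarity, or values from a user file (see
#' [compute_node_weights()]). The weights drive the node-weighted
#' centralities of [node_weighted_metrics()].
#'
#' @inheritParams build_aacen
#' @param weight_mode Node-weight mode or custom weight file path.
#' @param weight_file Custom weight file when `weight_mode = "custom_file"`.
#' @return An `aan` with `model_type = "NACEN"` and a `weight` node column.
#' @export
build_nacen <- function(s, table = load_energy_table(), e_thresh = 0,
                        d_cutoff = 8.0, weight_mode = "polarity",
                        weight_file = NULL, exclude_adjacent = 2,
                        atom_mode = "calpha", lr_sep = 12) {
  if (any(is.na(s$residues$ss[s$residues$kind == "amino_acid"]))) {
    s <- assign_secondary_structure(s)
  }
  net <- build_aacen(s, table, e_thresh = e_thresh, d_cutoff = d_cutoff,
                     exclude_adjacent = exclude_adjacent,
                     atom_mode = atom_mode, lr_sep = lr_sep)
  w <- compute_node_weights(s, mode = weight_mode, file = weight_file)
  if (!setequal(names(w), net$nodes$node_id)) {
    stop("missing-weight error: weight map does not cover the node set")
  }
  net$model_type <- "NACEN"
  net$nodes$weight <- unname(w[net$nodes$node_id])
  net$params$weight_mode <- if (is.null(weight_file)) weight_mode else
    paste0("custom_file:", weight_file)
  net
}

#' Min-max normalisation of edge contact energies
#'
#' Maps the absolute contact energies |e_ij| of a network's edges onto edge
#' weights: the edge(s) attaining the minimum |e| get weight 0.0001 exactly;
#' every other edge gets (|e| - |e|_min) / (|e|_max - |e|_min), so the
#' maximum-|e| edge(s) get exactly 1. Extrema are taken over the supplied
#' energies (per network). When all energies are equal every edge attains
#' the minimum and all weights are 0.0001.
#'
#' @param energies Numeric vector of strictly negative contact energies.
#' @return Numeric vector of edge weights.
#' @export
normalize_edge_weights <- function(energies) {
  if (length(energies) == 0) return(numeric(0))
  if (any(!is.finite(energies)) || any(energies >= 0)) {
    stop("contract violation: edge energies must be finite and strictly ",
         "negative")
  }
  a <- abs(energies)
  amin <- min(a)
  amax <- max(a)
  w <- rep(1e-04, length(a))
  not_min <- a != amin
  if (any(not_min)) w[not_min] <- (a[not_min] - amin) / (amax - amin)
  w
}

#' Build an edge-weighted amino acid contact energy network (EACEN)
#'
#' The edge set is identical to [build_aacen()]; each edge carries the
#' min-max-normalised absolute contact energy as weight (see
#' [normalize_edge_weights()]), and the adjacency matrix holds the weights
#' (0 for non-edges).
#'
#' @inheritParams build_aacen
#' @return An `aan` with `model_type = "EACEN"` and weighted edges.
#' @export
build_eacen <- function(s, table = load_energy_table(), e_thresh = 0,
                        d_cutoff = 8.0, exclude_adjacent = 2,
                        atom_mode = "calpha", lr_sep = 12) {
  net <- build_aacen(s, table, e_thresh = e_thresh, d_cutoff = d_cutoff,
                     exclude_adjacent = exclude_adjacent,
                     atom_mode = atom_mode, lr_sep = lr_sep)
  net$model_type <- "EACEN"
  if (nrow(net$edges) > 0) {
    w <- normalize_edge_weights(net$edges$energy)
    net$edges$weight <- w
    idx_i <- match(net$edges$node_i, net$nodes$node_id)
    idx_j <- match(net$edges$node_j, net$nodes$node_id)
    net$AM[cbind(idx_i, idx_j)] <- w
    net$AM[cbind(idx_j, idx_i)] <- w
  }
  net
}

# nucleotide representative atoms: P, C4* (sugar), C2 (base); both PDB v2
# (C4*) and v3 (C4') sugar-atom spellings are accepted
.nucleotide_nodes <- function(s) {
  nt <- s$residues[s$residues$kind == "nucleotide", , drop = FALSE]
  if (nrow(nt) == 0) {
    return(list(nodes = NULL, skipped = 0L))
  }
  roles <- list(P = "P", `C4*` = c("C4'", "C4*"), C2 = "C2")
  rows <- list()
  skipped <- 0L
  for (r in seq_len(nrow(nt))) {
    sel <- s$atoms$chain == nt$chain[r] & s$atoms$resno == nt$resno[r] &
      s$atoms$icode == nt$icode[r]
    at <- s$atoms[sel, , drop = FALSE]
    for (role in names(roles)) {
      hit <- which(at$atom %in% roles[[role]])
      if (length(hit) == 0) {
        skipped <- skipped + 1L
        next
      }
      a <- at[hit[1], ]
      rows[[length(rows) + 1]] <- data.frame(
        node_id = paste0(nt$node_id[r], ":", role), label = nt$resname[r],
        chain = nt$chain[r], resno = nt$resno[r], icode = nt$icode[r],
        node_kind = role, ss = NA_character_,
        x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    }
  }
  list(nodes = if (length(rows)) do.call(rbind, rows) else NULL,
       skipped = skipped)
}

#' Build a C-alpha distance-based network
#'
#' Amino-acid residues contribute one node at their C-alpha atom; each
#' nucleotide of a DNA/RNA chain contributes up to three nodes at its P,
#' C4* (sugar) and C2 (base) atoms (atoms absent from the coordinates, e.g.
#' a 5'-terminal phosphate, are skipped and counted in the run log). An edge
#' joins two nodes when their distance is strictly below `d_cutoff`. The
#' same-chain sequence-adjacency exclusion applies to amino-acid node pairs
#' only; nucleotide-derived nodes, including the three nodes of one
#' nucleotide, are linked purely by distance, and inter-chain edges are
#' always allowed.
#'
#' @param s A `structure_model`.
#' @param d_cutoff Distance threshold in Angstrom (strict).
#' @param exclude_adjacent Same-chain amino-acid sequence-separation
#'   exclusion.
#' @param lr_sep Sequence separation labelling an edge long-range.
#' @return An `aan` with `model_type = "CALPHA"`.
#' @export
build_calpha <- function(s, d_cutoff = 7.0, exclude_adjacent = 2,
                         lr_sep = 12) {
  stopifnot(inherits(s, "structure_model"), d_cutoff > 0)
  aa_nodes <- .aa_node_table(s)
  if (nrow(aa_nodes) > 0) {
    xyz <- .ca_coords(s)
    aa_nodes$x <- xyz[, 1]; aa_nodes$y <- xyz[, 2]; aa_nodes$z <- xyz[, 3]
  } else {
    aa_nodes$x <- aa_nodes$y <- aa_nodes$z <- numeric(0)
  }
  nuc <- .nucleotide_nodes(s)
  nodes <- rbind(aa_nodes, nuc$nodes)
  if (is.null(nodes) || nrow(nodes) == 0) {
    stop("empty-network error: structure has no representable nodes")
  }
  rownames(nodes) <- NULL
  d <- as.matrix(stats::dist(as.matrix(nodes[, c("x", "y", "z")])))
  pairs <- which(upper.tri(d) & d < d_cutoff, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    both_aa <- nodes$node_kind[pairs[, 1]] == "amino_acid" &
      nodes$node_kind[pairs[, 2]] == "amino_acid"
    same_chain <- nodes$chain[pairs[, 1]] == nodes$chain[pairs[, 2]]
    sep <- abs(nodes$resno[pairs[, 1]] - nodes$resno[pairs[, 2]])
    keep <- !(both_aa & same_chain & sep < exclude_adjacent)
    pairs <- pairs[keep, , drop = FALSE]
  }
  ed <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   energy = rep(NA_real_, nrow(pairs)),
                   distance = as.numeric(d[pairs]),
                   weight = rep(1, nrow(pairs)))
  ed$long_range <- .label_long_range(nodes, ed, lr_sep)
  xyz_cols <- c("x", "y", "z")
  log <- if (nuc$skipped > 0) {
    paste0("skipped ", nuc$skipped,
           " nucleotide representative atom(s) absent from coordinates")
  } else character()
  .make_aan("CALPHA", nodes[, setdiff(names(nodes), xyz_cols)], ed,
            params = list(d_cutoff = d_cutoff,
                          exclude_adjacent = exclude_adjacent,
                          lr_sep = lr_sep),
            log = log)
}

#' @export
print.aan <- function(x, ...) {
  cat("aan: ", x$model_type, " network, ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  if (!is.null(x$nodes$weight)) {
    cat("  node weights: [", format(min(x$nodes$weight), digits = 4), ", ",
        format(max(x$nodes$weight), digits = 4), "]\n", sep = "")
  }
  if (x$model_type == "EACEN" && nrow(x$edges) > 0) {
    cat("  edge weights: [", format(min(x$edges$weight), digits = 4), ", ",
        format(max(x$edges$weight), digits = 4), "]\n", sep = "")
  }
  if (!is.null(x$provenance)) cat("  energy table:", x$provenance, "\n")
  invisible(x)
}

#' @export
summary.aan <- function(object, ...) {
  nm <- network_metrics(object)
  cat("aan summary (", object$model_type, ")\n", sep = "")
  print(nm, row.names = FALSE)
  invisible(nm)
}

#' Plot an amino-acid network
#'
#' Thin wrapper around igraph plotting; nodes are coloured by chain and
#' scaled by degree.
#'
#' @param x An `aan`.
#' @param ... Passed to `plot.igraph`.
#' @export
plot.aan <- function(x, ...) {
  g <- as_igraph(x)
  chains <- factor(x$nodes$chain)
  igraph::V(g)$color <- grDevices::rainbow(nlevels(chains))[as.integer(chains)]
  deg <- igraph::degree(g)
  igraph::V(g)$size <- 3 + 10 * deg / max(1, max(deg))
  plot(g, vertex.label = NA, ...)
  invisible(x)
}
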