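# Environment-dependent residue contact energies (ERCE): the 60-letter
# alphabet (20 amino acids x 3 secondary-structure states), table loading and
# validation, pairwise lookups, and geometric candidate contacts.

.ss_code <- c(helix = "H", strand = "E", coil = "C")

#' Labels of the 60-letter residue-environment alphabet
#'
#' @return Character vector `"ALA_H", "ALA_E", "ALA_C", "ARG_H", ...` of
#'   length 60 (residue type x secondary-structure state).
#' @export
energy_labels <- function() {
  as.vector(t(outer(amino_acids(), c("H", "E", "C"), paste, sep = "_")))
}

#' Load and validate a contact-energy table
#'
#' The table is a symmetric 60x60 matrix of pairwise contact energies over
#' the residue-environment alphabet (see [energy_labels()]). The file format
#' is TSV with a header row and first column holding the `RES_SS` labels
#' (e.g. `ALA_H`, `GLY_C`). With `source = "default"` the table shipped with
#' the package is loaded: a synthetic baseline built from Miyazawa-Jernigan
#' (1996) contact energies by the additive approximation
#' `e_ij = (e_ii + e_jj)/2`, mean-centred so that contacts more favourable
#' than the average score negative, and replicated across the three
#' secondary-structure states. It stands in for environment-dependent tables
#' published elsewhere; supply your own file to use one.
#'
#' @param source `"default"` or a path to a table file.
#' @return An object of class `energy_table`: the validated matrix with a
#'   `provenance` attribute.
#' @export
load_energy_table <- function(source = "default") {
  if (identical(source, "default")) {
    path <- system.file("extdata", "erce_default_synthetic.tsv",
                        package = "aanet", mustWork = TRUE)
    provenance <- paste(
      "synthetic default: additive Miyazawa-Jernigan (1996) contact",
      "energies, mean-centred, replicated across secondary-structure states")
  } else {
    path <- source
    if (!file.exists(path)) stop("energy table file not found: ", path)
    provenance <- paste0("user file: ", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  as_energy_table(m, provenance = provenance)
}

#' Construct an energy_table from a labelled matrix
#'
#' Validates completeness (all 3600 entries finite over the 60-label
#' alphabet) and symmetry (tolerance 1e-9).
#'
#' @param m Numeric 60x60 matrix with [energy_labels()] dimnames (any order).
#' @param provenance Free-text provenance recorded in outputs.
#' @return An `energy_table`.
#' @export
as_energy_table <- function(m, provenance = "unspecified") {
  labels <- energy_labels()
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("validation error: energy table must have RES_SS row/column labels")
  }
  missing_lab <- setdiff(labels, rownames(m))
  if (length(missing_lab) > 0 || length(setdiff(labels, colnames(m))) > 0) {
    stop("validation error: energy table lacks label(s): ",
         paste(utils::head(unique(c(missing_lab,
                                    setdiff(labels, colnames(m)))), 5),
               collapse = ", "))
  }
  m <- m[labels, labels]
  if (any(!is.finite(m))) {
    stop("validation error: energy table has non-finite entries")
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9) {
    bad <- which(abs(m - t(m)) == asym, arr.ind = TRUE)[1, ]
    stop("validation error: energy table asymmetric at (",
         labels[bad[1]], ", ", labels[bad[2]], "): |a-b| = ",
         format(asym))
  }
  m <- (m + t(m)) / 2 # remove sub-tolerance rounding asymmetry
  structure(m, class = c("energy_table", "matrix", "array"),
            provenance = provenance)
}

#' @export
print.energy_table <- function(x, ...) {
  cat("energy_table: 60x60 residue-environment contact energies\n")
  cat("  provenance:", attr(x, "provenance"), "\n")
  cat("  range: [", format(min(x), digits = 4), ", ",
      format(max(x), digits = 4), "], ",
      sum(x[upper.tri(x, diag = TRUE)] < 0),
      " of 1830 unique pairs negative\n", sep = "")
  invisible(x)
}

.energy_label <- function(resname, ss) {
  code <- .ss_code[ss]
  if (any(is.na(code))) {
    stop("residue(s) without assigned secondary structure; run ",
         "assign_secondary_structure() first")
  }
  paste0(resname, "_", code)
}

#' Pairwise contact energy of two residues
#'
#' Looks up the table entry for the (residue type, secondary-structure
#' state) pair of each residue. Symmetric in its arguments and independent
#' of coordinates.
#'
#' @param res_i,res_j Single-row data frames (rows of
#'   `structure_model$residues`) or lists with `resname` and `ss`.
#' @param table An `energy_table`.
#' @return The contact energy e_ij (dimensionless contact-energy units).
#' @export
contact_energy <- function(res_i, res_j, table) {
  li <- .energy_label(res_i$resname, res_i$ss)
  lj <- .energy_label(res_j$resname, res_j$ss)
  if (!li %in% rownames(table)) stop("lookup error: no table row ", li)
  if (!lj %in% rownames(table)) stop("lookup error: no table row ", lj)
  unname(table[li, lj])
}

# representative-atom coordinate per amino-acid residue (C-alpha)
.ca_coords <- function(s) {
  at <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
  key <- .res_key(at$chain, at$resno, at$icode)
  aa <- s$residues[s$residues$kind == "amino_acid", , drop = FALSE]
  idx <- match(aa$node_id, key)
  cbind(x = at$x[idx], y = at$y[idx], z = at$z[idx])
}

#' Geometric candidate contacts between amino-acid residues
#'
#' All unordered amino-acid residue pairs whose representative-atom distance
#' is within `d_cutoff`, excluding self-pairs and, within a chain, pairs
#' closer in sequence than `exclude_adjacent` (default: |delta seq| < 2,
#' i.e. covalently bonded neighbours are never candidate contacts).
#'
#' @param s A `structure_model`.
#' @param d_cutoff Distance cutoff in Angstrom (inclusive).
#' @param exclude_adjacent Minimum same-chain sequence separation for a pair
#'   to be eligible; pairs with |delta seq| < `exclude_adjacent` are dropped.
#' @param atom_mode `"calpha"` (C-alpha distance, default) or `"heavy"`
#'   (minimum heavy-atom distance).
#' @return Data frame with columns `i`, `j` (indices into the amino-acid
#'   residue subset), `node_i`, `node_j`, `distance`.
#' @export
candidate_contacts <- function(s, d_cutoff = 8.0, exclude_adjacent = 2,
                               atom_mode = c("calpha", "heavy")) {
  stopifnot(inherits(s, "structure_model"), d_cutoff > 0)
  atom_mode <- match.arg(atom_mode)
  aa <- s$residues[s$residues$kind == "amino_acid", , drop = FALSE]
  n <- nrow(aa)
  if (n < 2) {
    return(data.frame(i = integer(), j = integer(), node_i = character(),
                      node_j = character(), distance = numeric()))
  }
  if (atom_mode == "calpha") {
    xyz <- .ca_coords(s)
    d <- as.matrix(stats::dist(xyz))
  } else {
    d <- .min_heavy_dist(s, aa)
  }
  pairs <- which(upper.tri(d) & d <= d_cutoff, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    same_chain <- aa$chain[pairs[, 1]] == aa$chain[pairs[, 2]]
    sep <- abs(aa$resno[pairs[, 1]] - aa$resno[pairs[, 2]])
    keep <- !(same_chain & sep < exclude_adjacent)
    pairs <- pairs[keep, , drop = FALSE]
  }
  out <- data.frame(
    i = pairs[, 1], j = pairs[, 2],
    node_i = aa$node_id[pairs[, 1]], node_j = aa$node_id[pairs[, 2]],
    distance = d[pairs], stringsAsFactors = FALSE)
  out[order(out$i, out$j), , drop = FALSE]
}

# minimum heavy-atom distance matrix between amino-acid residues
.min_heavy_dist <- function(s, aa) {
  at <- s$atoms[toupper(s$atoms$element) != "H", , drop = FALSE]
  key <- .res_key(at$chain, at$resno, at$icode)
  ridx <- match(key, aa$node_id)
  keep <- !is.na(ridx)
  at <- at[keep, , drop = FALSE]
  ridx <- ridx[keep]
  n <- nrow(aa)
  d <- matrix(Inf, n, n)
  dall <- as.matrix(stats::dist(as.matrix(at[, c("x", "y", "z")])))
  for (a in seq_len(n)) {
    ia <- which(ridx == a)
    for (b in seq_len(n)) {
      if (b <= a) next
      ib <- which(ridx == b)
      d[a, b] <- d[b, a] <- min(dall[ia, ib])
    }
  }
  diag(d) <- 0
  d
}
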