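# Synthetic structure generators: small peptides, nucleic-acid chains and
# protein-RNA complexes with ideal geometry, emitted as PDB-format text, plus
# a toy contact-energy table. Identical arguments (incl. seed) give
# byte-identical output, so every pipeline stage is testable offline.

.fixture_seq <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE",
                  "LYS", "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER",
                  "THR", "VAL", "TRP", "TYR")

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                           element, icode = "") {
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, resname, chain, resno,
          if (nzchar(icode)) icode else " ",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

# backbone (N, CA, C, O) of one chain at fixed phi/psi, ideal bond geometry
.peptide_coords <- function(length, phi, psi, seed = 1, jitter = 0,
                            origin = c(0, 0, 0)) {
  n_xyz <- vector("list", length)
  ca_xyz <- vector("list", length)
  c_xyz <- vector("list", length)
  o_xyz <- vector("list", length)
  n_xyz[[1]] <- c(0, 0, 0)
  ca_xyz[[1]] <- c(1.458, 0, 0)
  ang <- (180 - 111.2) * pi / 180
  c_xyz[[1]] <- ca_xyz[[1]] + 1.525 * c(cos(ang), sin(ang), 0)
  for (i in seq_len(length)[-1]) {
    n_xyz[[i]] <- .place_atom(n_xyz[[i - 1]], ca_xyz[[i - 1]],
                              c_xyz[[i - 1]], 1.329, 116.2, psi)
    ca_xyz[[i]] <- .place_atom(ca_xyz[[i - 1]], c_xyz[[i - 1]], n_xyz[[i]],
                               1.458, 121.7, 180)
    c_xyz[[i]] <- .place_atom(c_xyz[[i - 1]], n_xyz[[i]], ca_xyz[[i]],
                              1.525, 111.2, phi)
  }
  for (i in seq_len(length)) {
    ref <- if (i < length) n_xyz[[i + 1]] else n_xyz[[i]]
    tors <- if (i < length) 180 else 0
    o_xyz[[i]] <- .place_atom(ref, ca_xyz[[i]], c_xyz[[i]], 1.231, 120.8,
                              tors)
  }
  coords <- list(N = n_xyz, CA = ca_xyz, C = c_xyz, O = o_xyz)
  if (jitter > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    for (a in names(coords)) {
      coords[[a]] <- lapply(coords[[a]],
                            function(p) p + stats::rnorm(3, 0, jitter))
    }
  }
  lapply(coords, function(l) lapply(l, function(p) p + origin))
}

.peptide_lines <- function(length, phi, psi, chain = "A", seed = 1,
                           jitter = 0, origin = c(0, 0, 0), serial0 = 0,
                           resno0 = 0) {
  xyz <- .peptide_coords(length, phi, psi, seed = seed, jitter = jitter,
                         origin = origin)
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(length)) {
    resname <- .fixture_seq[((i - 1) %% 20) + 1]
    for (a in c("N", "CA", "C", "O")) {
      serial <- serial + 1
      lines <- c(lines, .pdb_atom_line(serial, a, resname, chain,
                                       resno0 + i, xyz[[a]][[i]],
                                       substr(a, 1, 1)))
    }
  }
  list(lines = c(lines, sprintf("TER   %5d      %-3s %1s%4d", serial + 1,
                                .fixture_seq[((length - 1) %% 20) + 1],
                                chain, resno0 + length)),
       serial = serial + 1)
}

#' Generate a synthetic peptide (or two-chain complex) in PDB format
#'
#' Backbone-only (N, CA, C, O) chains built from ideal bond geometry at
#' fixed dihedrals: alpha-helical (phi = -57, psi = -47) or fully extended
#' (phi = psi = 180). Residue types cycle through a fixed 20-residue
#' sequence. `two_chain_complex` emits two helical chains (A, B) offset so
#' that inter-chain contacts exist. Identical arguments give byte-identical
#' text.
#'
#' @param kind `"helix_peptide"`, `"extended_peptide"` or
#'   `"two_chain_complex"`.
#' @param length Residues per chain (>= 1).
#' @param seed Seed for the optional coordinate jitter.
#' @param jitter Gaussian jitter (sd, Angstrom) on every coordinate; 0 keeps
#'   the ideal geometry.
#' @return PDB-format text (one string).
#' @export
make_peptide <- function(kind = c("helix_peptide", "extended_peptide",
                                  "two_chain_complex"),
                         length = 10, seed = 1, jitter = 0) {
  kind <- match.arg(kind)
  if (length < 1) stop("argument error: length must be >= 1")
  if (kind == "extended_peptide") {
    chain_a <- .peptide_lines(length, 180, 180, "A", seed, jitter)
    lines <- chain_a$lines
  } else {
    chain_a <- .peptide_lines(length, -57, -47, "A", seed, jitter)
    lines <- chain_a$lines
    if (kind == "two_chain_complex") {
      chain_b <- .peptide_lines(length, -57, -47, "B", seed + 1, jitter,
                                origin = c(0, 6.5, 0),
                                serial0 = chain_a$serial)
      lines <- c(lines, chain_b$lines)
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# coarse A-form-like helical trace: three representative atoms per
# nucleotide at plausible radii/rise
.nucleic_lines <- function(length, chain = "B", origin = c(0, 0, 0),
                           serial0 = 0, skip_5p = FALSE, seed = 1,
                           jitter = 0) {
  bases <- c("A", "U", "G", "C")
  twist <- 32.7 * pi / 180
  rise <- 2.81
  geom <- list(P = c(r = 8.8, dphi = 0, dz = 0),
               `C4'` = c(r = 7.2, dphi = 0.25, dz = 0.5),
               C2 = c(r = 4.3, dphi = 0.45, dz = 0.8))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(length)) {
    base <- bases[((i - 1) %% 4) + 1]
    phi0 <- (i - 1) * twist
    for (a in names(geom)) {
      if (a == "P" && i == 1 && skip_5p) next
      g <- geom[[a]]
      p <- c(g["r"] * cos(phi0 + g["dphi"]),
             g["r"] * sin(phi0 + g["dphi"]),
             (i - 1) * rise + g["dz"])
      if (jitter > 0) p <- p + stats::rnorm(3, 0, jitter)
      serial <- serial + 1
      lines <- c(lines, .pdb_atom_line(serial, a, base, chain, i,
                                       p + origin,
                                       if (a == "P") "P" else "C"))
    }
  }
  list(lines = c(lines, sprintf("TER   %5d      %-3s %1s%4d", serial + 1,
                                bases[((length - 1) %% 4) + 1], chain,
                                length)),
       serial = serial + 1)
}

#' Generate a synthetic nucleic-acid chain or protein-RNA complex
#'
#' Nucleotides carry the three representative atoms P, C4' (sugar) and C2
#' (base) on a coarse helical trace. `rna_hairpin` emits one RNA chain;
#' `protein_rna_complex` emits a helical peptide (chain A) placed against an
#' RNA chain (chain B) so that inter-molecular contacts exist.
#'
#' @param kind `"rna_hairpin"` or `"protein_rna_complex"`.
#' @param length Number of nucleotides (and, for the complex, of residues).
#' @param seed Seed for the optional jitter.
#' @param jitter Gaussian coordinate jitter (sd, Angstrom).
#' @param skip_5p Omit the 5'-terminal phosphate (common in real entries).
#' @return PDB-format text (one string).
#' @export
make_nucleic <- function(kind = c("rna_hairpin", "protein_rna_complex"),
                         length = 3, seed = 1, jitter = 0, skip_5p = FALSE) {
  kind <- match.arg(kind)
  if (length < 1) stop("argument error: length must be >= 1")
  if (kind == "rna_hairpin") {
    rna <- .nucleic_lines(length, "B", serial0 = 0, skip_5p = skip_5p,
                          seed = seed, jitter = jitter)
    return(paste(c(rna$lines, "END"), collapse = "\n"))
  }
  pep <- .peptide_lines(length, -57, -47, "A", seed, jitter,
                        origin = c(12, 0, 0))
  rna <- .nucleic_lines(length, "B", serial0 = pep$serial,
                        skip_5p = skip_5p, seed = seed + 1, jitter = jitter)
  paste(c(pep$lines, rna$lines, "END"), collapse = "\n")
}

#' Toy contact-energy table for tests
#'
#' A complete symmetric 60x60 table with a deterministic seed-controlled mix
#' of negative and positive entries, so edge thresholding is exercised
#' without depending on the shipped default table's values.
#'
#' @param seed Integer seed.
#' @param frac_negative Approximate fraction of negative entries.
#' @return An `energy_table`.
#' @export
make_toy_energy_table <- function(seed = 1, frac_negative = 0.6) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  labels <- energy_labels()
  m <- matrix(0, 60, 60, dimnames = list(labels, labels))
  up <- upper.tri(m, diag = TRUE)
  vals <- stats::runif(sum(up), 0, 3)
  neg <- stats::runif(sum(up)) < frac_negative
  vals[neg] <- -vals[neg]
  m[up] <- vals
  m <- m + t(m) - diag(diag(m))
  as_energy_table(m, provenance = paste0("toy table (seed ", seed, ")"))
}

#' Synthetic parser-regression PDB text
#'
#' A small hand-constructed PDB literal (not a real PDB entry) exercising
#' parser paths: multi-model records (only model 1 must be kept), alternate
#' locations (highest occupancy wins), an MSE selenomethionine mapped to
#' MET, waters and a non-polymer ligand (both excluded), and TER records.
#'
#' @return PDB-format text (one string).
#' @export
synthetic_pdb_text <- function() {
  paste(c(
    "HEADER    SYNTHETIC TEST PEPTIDE",
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N  AGLY A   2       3.332   1.536   0.000  0.60  0.00           N",
    "ATOM      6  N  BGLY A   2       3.340   1.540   0.100  0.40  0.00           N",
    "ATOM      7  CA  GLY A   2       4.016   2.820   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.530   2.660   0.120  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.060   1.550   0.220  1.00  0.00           O",
    "HETATM   10  N   MSE A   3       6.250   3.790   0.100  1.00  0.00           N",
    "HETATM   11  CA  MSE A   3       7.700   3.790   0.200  1.00  0.00           C",
    "HETATM   12  C   MSE A   3       8.280   5.200   0.250  1.00  0.00           C",
    "HETATM   13  O   MSE A   3       7.560   6.200   0.230  1.00  0.00           O",
    "ATOM     14  N   SER A   4       9.610   5.280   0.330  1.00  0.00           N",
    "ATOM     15  CA  SER A   4      10.310   6.560   0.380  1.00  0.00           C",
    "ATOM     16  C   SER A   4      11.820   6.350   0.470  1.00  0.00           C",
    "ATOM     17  O   SER A   4      12.330   5.230   0.530  1.00  0.00           O",
    "TER      18      SER A   4",
    "HETATM   19  O   HOH A 101      15.000  15.000  15.000  1.00  0.00           O",
    "HETATM   20 ZN    ZN A 102      18.000  18.000  18.000  1.00  0.00          ZN",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1      99.000  99.000  99.000  1.00  0.00           N",
    "ENDMDL",
    "END"), collapse = "\n")
}
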