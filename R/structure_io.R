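# Structure parsing, residue classification, secondary structure and node
# weights. A structure_model is the single source for all network builders.

.res_key <- function(chain, resno, icode) {
  ic <- ifelse(is.na(icode) | icode == "", "", paste0(":", icode))
  paste0(chain, ":", resno, ic)
}

#' Parse a macromolecular structure in PDB format
#'
#' Reads a PDB file (or raw PDB text, or a 4-character PDB code fetched from
#' RCSB when `fetch = TRUE`), keeps the first model of multi-model entries,
#' resolves alternate locations to the highest-occupancy conformer, maps
#' common modified residues to their parent type (e.g. MSE to MET) and
#' classifies every polymer residue as amino acid, nucleotide or other.
#' Waters and non-polymer heteroatoms are excluded.
#'
#' @param source Path to a `.pdb` file, a character string containing PDB
#'   records (detected by embedded newlines), or a 4-character PDB code.
#' @param fetch Allow downloading by PDB code from RCSB. With `fetch = FALSE`
#'   a code that is not also a local file is an error.
#' @return An object of class `structure_model`: a list with `structure_id`,
#'   `source` (`"file"` or `"fetched"`), `atoms` (one row per atom: chain,
#'   resno, icode, resname, atom, element, x, y, z) and `residues` (one row
#'   per residue: chain, resno, icode, resname, kind, ss, node_id).
#' @export
parse_structure <- function(source, fetch = TRUE) {
  stopifnot(is.character(source), length(source) == 1)
  origin <- "file"
  if (grepl("\n", source, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(source, "\n", fixed = TRUE)[[1]], path)
    structure_id <- "inline"
  } else if (file.exists(source)) {
    path <- source
    structure_id <- sub("\\.(pdb|ent)$", "", basename(source),
                        ignore.case = TRUE)
  } else if (grepl("^[0-9][A-Za-z0-9]{3}$", source)) {
    if (!fetch) {
      stop("parse error: '", source, "' is not a local file and fetching ",
           "by PDB code is disabled (fetch = FALSE)")
    }
    path <- fetch_pdb(source)
    origin <- "fetched"
    structure_id <- toupper(source)
  } else {
    stop("parse error: '", source,
         "' is neither a readable PDB file nor a 4-character PDB code")
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stop("parse error in '", path, "': ", conditionMessage(e))
    })

  at <- pdb$atom
  # first model only: bio3d with multi = FALSE already returns model 1
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$resid <- toupper(at$resid)

  # drop waters outright
  at <- at[!(at$resid %in% .waters), , drop = FALSE]

  # map modified residues recorded as HETATM (e.g. MSE) onto parent types
  alias_hit <- at$resid %in% names(.res_alias)
  at$resid[alias_hit] <- .res_alias[at$resid[alias_hit]]

  kind0 <- ifelse(at$resid %in% amino_acids(), "amino_acid",
                  ifelse(at$resid %in% .nucleotides, "nucleotide", "other"))
  # non-polymer heteroatoms (ions, ligands) are excluded; polymer residues
  # typed as ATOM but of unknown chemistry are retained as "other"
  drop_het <- at$type == "HETATM" & kind0 == "other"
  if (any(drop_het)) {
    dropped <- unique(at$resid[drop_het])
    message("excluding ", length(dropped), " non-polymer hetero residue type(s): ",
            paste(dropped, collapse = ", "))
    at <- at[!drop_het, , drop = FALSE]
    kind0 <- kind0[!drop_het]
  }
  nonstd <- at$type == "ATOM" & kind0 == "other"
  if (any(nonstd)) {
    warning("non-standard polymer residue(s) kept as kind 'other': ",
            paste(unique(at$resid[nonstd]), collapse = ", "))
  }
  if (nrow(at) == 0) {
    stop("empty-structure error: '", structure_id,
         "' contains zero polymer residues")
  }

  # altloc: keep the highest-occupancy conformer per (chain,res,atom)
  if (any(!is.na(at$alt) & at$alt != "")) {
    at$o[is.na(at$o)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -at$o, at$alt, method = "radix")
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)),
             , drop = FALSE]
  }

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = at$insert,
    resname = at$resid, atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1),
                     toupper(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  ord <- order(atoms$chain, atoms$resno, atoms$icode, method = "radix")
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL

  rkey <- .res_key(atoms$chain, atoms$resno, atoms$icode)
  first <- !duplicated(rkey)
  residues <- data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    icode = atoms$icode[first], resname = atoms$resname[first],
    stringsAsFactors = FALSE)
  residues$kind <- ifelse(residues$resname %in% amino_acids(), "amino_acid",
                          ifelse(residues$resname %in% .nucleotides,
                                 "nucleotide", "other"))
  residues$ss <- NA_character_
  residues$node_id <- .res_key(residues$chain, residues$resno, residues$icode)
  if (anyDuplicated(residues$node_id)) {
    stop("parse error: duplicate residue identifiers: ",
         paste(residues$node_id[duplicated(residues$node_id)], collapse = ", "))
  }
  rownames(residues) <- NULL

  # amino-acid residues retained for network building must have a C-alpha
  aa <- residues$kind == "amino_acid"
  has_ca <- residues$node_id %in%
    .res_key(atoms$chain, atoms$resno, atoms$icode)[atoms$atom == "CA" &
                                                      is.finite(atoms$x)]
  if (any(aa & !has_ca)) {
    warning("dropping ", sum(aa & !has_ca),
            " amino-acid residue(s) without C-alpha coordinates")
    keep <- !(aa & !has_ca)
    drop_ids <- residues$node_id[!keep]
    residues <- residues[keep, , drop = FALSE]
    atoms <- atoms[!(.res_key(atoms$chain, atoms$resno, atoms$icode) %in%
                       drop_ids), , drop = FALSE]
    rownames(residues) <- rownames(atoms) <- NULL
  }
  if (nrow(residues) == 0) {
    stop("empty-structure error: '", structure_id,
         "' contains zero usable polymer residues")
  }

  structure(list(structure_id = structure_id, source = origin,
                 atoms = atoms, residues = residues),
            class = "structure_model")
}

#' Download a PDB entry from RCSB
#'
#' @param code 4-character PDB code.
#' @param dest Destination file; defaults to a tempfile.
#' @return Path to the downloaded file.
#' @export
fetch_pdb <- function(code, dest = tempfile(fileext = ".pdb")) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", code))
  url <- paste0("https://files.rcsb.org/download/", toupper(code), ".pdb")
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest)) {
    stop("resource error: could not fetch PDB entry '", code, "' from RCSB")
  }
  dest
}

#' @export
print.structure_model <- function(x, ...) {
  k <- table(factor(x$residues$kind,
                    levels = c("amino_acid", "nucleotide", "other")))
  cat("structure_model '", x$structure_id, "' (", x$source, ")\n", sep = "")
  cat("  chains:   ", paste(unique(x$residues$chain), collapse = ", "), "\n")
  cat("  residues: ", nrow(x$residues), " (", k[["amino_acid"]],
      " amino acid, ", k[["nucleotide"]], " nucleotide, ", k[["other"]],
      " other)\n", sep = "")
  cat("  atoms:    ", nrow(x$atoms), "\n", sep = "")
  if (!all(is.na(x$residues$ss))) {
    s <- table(factor(x$residues$ss, levels = c("helix", "strand", "coil")))
    cat("  secondary structure: ", s[["helix"]], " helix / ", s[["strand"]],
        " strand / ", s[["coil"]], " coil\n", sep = "")
  }
  invisible(x)
}

# Backbone phi/psi angles per amino-acid residue of one chain, NA at termini
# or across missing backbone atoms.
.chain_phipsi <- function(atoms, residues_chain) {
  n <- nrow(residues_chain)
  get_xyz <- function(i, name) {
    sel <- atoms$chain == residues_chain$chain[i] &
      atoms$resno == residues_chain$resno[i] &
      atoms$icode == residues_chain$icode[i] &
      atoms$atom == name
    if (!any(sel)) return(NULL)
    as.numeric(atoms[which(sel)[1], c("x", "y", "z")])
  }
  phi <- psi <- rep(NA_real_, n)
  bb <- lapply(seq_len(n), function(i) {
    list(N = get_xyz(i, "N"), CA = get_xyz(i, "CA"), C = get_xyz(i, "C"))
  })
  ok <- vapply(bb, function(b) !any(vapply(b, is.null, TRUE)), TRUE)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    if (i > 1 && ok[i - 1]) {
      # peptide bond must be real, not a chain break
      if (.vnorm(bb[[i]]$N - bb[[i - 1]]$C) < 2.5) {
        phi[i] <- .dihedral(bb[[i - 1]]$C, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
      }
    }
    if (i < n && ok[i + 1]) {
      if (.vnorm(bb[[i + 1]]$N - bb[[i]]$C) < 2.5) {
        psi[i] <- .dihedral(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, bb[[i + 1]]$N)
      }
    }
  }
  list(phi = phi, psi = psi)
}

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' Classifies every amino-acid residue as helix, strand or coil from its
#' phi/psi backbone dihedral angles: helix for phi in (-145, -10) and psi in
#' (-90, 45), strand for phi in (-180, -45) with psi in (90, 180] or
#' [-180, -120). Raw assignments are smoothed by minimum run lengths (4 for
#' helix, 2 for strand, shorter runs revert to coil). Residues with missing
#' backbone atoms, chain termini and isolated residues default to coil.
#' The classification is deterministic in the coordinates.
#'
#' @param s A `structure_model`.
#' @return The model with `residues$ss` filled for all amino-acid residues.
#' @export
assign_secondary_structure <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  res <- s$residues
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch & res$kind == "amino_acid")
    if (length(idx) == 0) next
    rc <- res[idx, , drop = FALSE]
    ang <- .chain_phipsi(s$atoms, rc)
    # the +/-180 wrap point belongs to the extended region
    ang$phi <- ifelse(!is.na(ang$phi) & ang$phi > 175, ang$phi - 360,
                      ang$phi)
    raw <- rep("coil", length(idx))
    helix <- !is.na(ang$phi) & !is.na(ang$psi) &
      ang$phi > -145 & ang$phi < -10 & ang$psi > -90 & ang$psi < 45
    strand <- !is.na(ang$phi) & !is.na(ang$psi) &
      ang$phi >= -180 & ang$phi < -45 &
      (ang$psi > 90 | ang$psi < -120)
    raw[strand] <- "strand"
    raw[helix] <- "helix"
    raw <- .smooth_ss(raw, min_helix = 4, min_strand = 2)
    res$ss[idx] <- raw
  }
  s$residues <- res
  s
}

# revert helix/strand runs shorter than the minimum to coil
.smooth_ss <- function(states, min_helix = 4, min_strand = 2) {
  r <- rle(states)
  short <- (r$values == "helix" & r$lengths < min_helix) |
    (r$values == "strand" & r$lengths < min_strand)
  r$values[short] <- "coil"
  inverse.rle(r)
}

#' Compute per-residue node weights
#'
#' Resolves one numeric weight for every amino-acid residue of a structure.
#' `mass`, `hydrophobicity` and `polarity` are pure per-residue-type lookups
#' (see [residue_scale()]); `sas` is the structure-dependent relative solvent
#' accessibility from a Shrake-Rupley calculation normalised by theoretical
#' maxima; `custom_file` reads a whitespace-separated text file with lines
#' `chain resnum weight` (`#` comments allowed).
#'
#' @param s A `structure_model`.
#' @param mode One of `"sas"`, `"mass"`, `"hydrophobicity"`, `"polarity"`,
#'   `"custom_file"`, or a file path (implies `custom_file`).
#' @param file Path of the custom weight file when `mode = "custom_file"`.
#' @return Named numeric vector over exactly the amino-acid residue node ids.
#' @export
compute_node_weights <- function(s, mode = "polarity", file = NULL) {
  stopifnot(inherits(s, "structure_model"))
  if (length(mode) == 1 && !mode %in%
      c("sas", "mass", "hydrophobicity", "polarity", "custom_file") &&
      file.exists(mode)) {
    file <- mode
    mode <- "custom_file"
  }
  mode <- match.arg(mode,
                    c("sas", "mass", "hydrophobicity", "polarity",
                      "custom_file"))
  aa <- s$residues[s$residues$kind == "amino_acid", , drop = FALSE]
  if (nrow(aa) == 0) stop("structure has no amino-acid residues")

  if (mode %in% c("mass", "hydrophobicity", "polarity")) {
    scale <- residue_scale(mode)
    w <- unname(scale[aa$resname])
  } else if (mode == "sas") {
    rsa <- relative_sasa(s)
    w <- unname(rsa[aa$node_id])
  } else {
    if (is.null(file) || !file.exists(file)) {
      stop("custom_file mode requires a readable weight file")
    }
    w <- .read_weight_file(file, aa)
  }
  if (any(!is.finite(w))) {
    stop("missing-weight error: no finite weight for residue(s): ",
         paste(aa$node_id[!is.finite(w)], collapse = ", "))
  }
  names(w) <- aa$node_id
  w
}

.read_weight_file <- function(file, aa) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("weight file '", file, "' has no data lines")
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad)) {
    stop("parse error in weight file '", file, "' at line(s): ",
         paste(which(bad), collapse = ", "))
  }
  chain <- vapply(parts, `[`, "", 1)
  resnum <- vapply(parts, `[`, "", 2)
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  if (any(is.na(val))) {
    stop("parse error: non-numeric weight in '", file, "' at line(s): ",
         paste(which(is.na(val)), collapse = ", "))
  }
  # resnum may carry an insertion code suffix, e.g. "52A"
  key <- paste0(chain, ":", sub("^([0-9-]+)([A-Za-z])$", "\\1:\\2", resnum))
  w <- val[match(aa$node_id, key)]
  if (any(is.na(w))) {
    stop("missing-weight error: weight file '", file,
         "' lacks residue(s): ",
         paste(aa$node_id[is.na(w)], collapse = ", "))
  }
  w
}
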