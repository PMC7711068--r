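# Shrake-Rupley solvent-accessible surface area and relative accessibility.

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral), the classic test-point construction for Shrake-Rupley.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface using deterministic
#' spiral test points. Hydrogens are ignored (PDB entries rarely carry them
#' and the vdW radii used are for heavy atoms).
#'
#' @param xyz Numeric matrix, one row per atom (x, y, z in Angstrom).
#' @param elements Character vector of element symbols, same length.
#' @param probe Probe radius in Angstrom; 1.4 approximates water.
#' @param n_points Test points per atom; more points, smoother areas.
#' @return Numeric vector of per-atom ASA in square Angstrom.
#' @export
shrake_rupley <- function(xyz, elements, probe = 1.4, n_points = 120) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) == length(elements))
  radii <- .vdw_radii[toupper(elements)]
  radii[is.na(radii)] <- 1.70 # unknown elements treated as carbon
  r <- unname(radii) + probe
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  if (n == 0) return(area)
  max_r <- max(r)
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can intersect atom i's
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + max_r)^2 & d2 > 0)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    test <- pts * r[i]
    test <- sweep(test, 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
          (test[, 3] - xyz[j, 3])^2
        free <- free & dj2 > r[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * r[i]^2
  }
  area
}

#' Relative solvent accessibility per residue
#'
#' Sums the Shrake-Rupley ASA of each amino-acid residue's heavy atoms and
#' divides by the residue type's theoretical maximum (Tien et al. 2013).
#' Values are capped at 1.2: exposed termini can slightly exceed 1.
#'
#' @param s A `structure_model`.
#' @param probe Probe radius in Angstrom.
#' @param n_points Shrake-Rupley test points per atom.
#' @return Named numeric vector of relative accessibilities in `[0, 1.2]`,
#'   one per amino-acid residue node id.
#' @export
relative_sasa <- function(s, probe = 1.4, n_points = 120) {
  stopifnot(inherits(s, "structure_model"))
  at <- s$atoms[toupper(s$atoms$element) != "H", , drop = FALSE]
  asa <- shrake_rupley(as.matrix(at[, c("x", "y", "z")]), at$element,
                       probe = probe, n_points = n_points)
  key <- .res_key(at$chain, at$resno, at$icode)
  per_res <- tapply(asa, key, sum)
  aa <- s$residues[s$residues$kind == "amino_acid", , drop = FALSE]
  total <- per_res[aa$node_id]
  total[is.na(total)] <- 0
  rsa <- unname(total) / .res_max_asa[aa$resname]
  rsa <- pmin(unname(rsa), 1.2)
  names(rsa) <- aa$node_id
  rsa
}
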