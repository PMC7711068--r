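# The four network builders and the edge-weight normalisation.

# a toy table whose sign structure we control completely: every pair gets
# energy `neg` except ALA-ALA pairs, which get `ala`
.signed_table <- function(neg = -1.2, ala = 0.3) {
  labels <- energy_labels()
  m <- matrix(neg, 60, 60, dimnames = list(labels, labels))
  ala_lab <- grep("^ALA_", labels, value = TRUE)
  m[ala_lab, ala_lab] <- ala
  as_energy_table(m, "signed toy")
}

test_that("AACEN rule: edge iff e_ij < threshold, binary adjacency, e=0 is no edge", {
  s <- assign_secondary_structure(parse_structure(make_peptide("helix_peptide", 10)))
  # all energies negative -> every candidate contact is an edge
  neg <- build_aacen(s, .signed_table(-1.2, -1.2))
  cand <- candidate_contacts(s, d_cutoff = 8)
  expect_identical(nrow(neg$edges), nrow(cand))
  expect_true(all(neg$AM %in% c(0, 1)))
  expect_identical(unname(neg$AM["A:1", "A:4"]),
                   as.numeric("A:1 A:4" %in% paste(cand$node_i, cand$node_j)))
  # all energies positive -> no edges
  pos <- build_aacen(s, .signed_table(0.3, 0.3))
  expect_identical(nrow(pos$edges), 0L)
  # boundary: e_ij = 0 exactly is NOT an edge (strict inequality)
  zero <- build_aacen(s, .signed_table(0, 0))
  expect_identical(nrow(zero$edges), 0L)
  # sweep of signs: only non-ALA pairs survive with the mixed table
  mix <- build_aacen(s, .signed_table(-1.2, 0.3))
  lab <- s$residues$resname[match(c(mix$edges$node_i, mix$edges$node_j),
                                  s$residues$node_id)]
  both_ala <- matrix(lab, ncol = 2)
  expect_false(any(both_ala[, 1] == "ALA" & both_ala[, 2] == "ALA"))
})

test_that("empty structures raise an empty-network error", {
  rna <- parse_structure(make_nucleic("rna_hairpin", 3))
  expect_error(build_aacen(rna, make_toy_energy_table(1)),
               "empty-network|no amino-acid")
})

test_that("edge-weight normalisation follows the min-max rule", {
  expect_equal(normalize_edge_weights(c(-1, -2, -3)), c(1e-04, 0.5, 1.0))
  # degenerate range: every edge attains the minimum
  expect_equal(normalize_edge_weights(c(-2, -2)), c(1e-04, 1e-04))
  expect_equal(normalize_edge_weights(-5), 1e-04)
  # ordering of the input is respected
  expect_equal(normalize_edge_weights(c(-3, -1, -2)), c(1.0, 1e-04, 0.5))
  expect_error(normalize_edge_weights(c(-1, 0.5)), "contract violation")
  expect_error(normalize_edge_weights(c(-1, 0)), "contract violation")
})

test_that("EACEN adjacency holds the normalised weights symmetrically", {
  # 5-residue collinear chain; table: all contacts negative with distinct
  # energies by residue type so we can hand-compute Eq-style weights
  s <- assign_secondary_structure(parse_structure(make_peptide("helix_peptide", 6)))
  t <- make_toy_energy_table(3, frac_negative = 1)
  net <- build_eacen(s, t)
  expect_gt(nrow(net$edges), 2)
  manual <- normalize_edge_weights(net$edges$energy)
  expect_equal(net$edges$weight, manual)
  for (k in seq_len(nrow(net$edges))) {
    expect_identical(net$AM[net$edges$node_i[k], net$edges$node_j[k]],
                     net$edges$weight[k])
    expect_identical(net$AM[net$edges$node_j[k], net$edges$node_i[k]],
                     net$edges$weight[k])
  }
  # extrema map to the printed constants
  expect_equal(min(net$edges$weight), 1e-04)
  expect_equal(max(net$edges$weight), 1)
  # non-contacting pairs stay 0
  expect_identical(unname(net$AM["A:1", "A:6"]), 0)
})

test_that("AACEN, NACEN and EACEN share an identical edge set", {
  for (seed in 1:20) {
    n <- 6 + (seed %% 7)
    s <- assign_secondary_structure(
      parse_structure(make_peptide("helix_peptide", n, seed = seed,
                                   jitter = 0.05)))
    t <- make_toy_energy_table(seed)
    a <- build_aacen(s, t)
    nn <- build_nacen(s, t, weight_mode = "mass")
    e <- build_eacen(s, t)
    key <- function(net) paste(net$edges$node_i, net$edges$node_j)
    expect_identical(key(nn), key(a))
    expect_identical(key(e), key(a))
    # unweighted skeleton of EACEN = AACEN
    expect_identical(e$AM != 0, a$AM != 0)
  }
})

test_that("NACEN carries exactly one weight per node", {
  s <- parse_structure(make_peptide("helix_peptide", 10))
  t <- make_toy_energy_table(2)
  net <- build_nacen(s, t, weight_mode = "polarity")
  expect_identical(net$model_type, "NACEN")
  expect_true(all(is.finite(net$nodes$weight)))
  pol <- residue_scale("polarity")
  expect_equal(net$nodes$weight, unname(pol[net$nodes$label]))
})

test_that("C-alpha network: node counts, strict threshold, nucleotide nodes", {
  pep <- parse_structure(make_peptide("helix_peptide", 9))
  net <- build_calpha(pep, 7)
  expect_identical(nrow(net$nodes), 9L)
  # strict threshold at the boundary
  mk2 <- function(d) paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    sprintf("ATOM      2  CA  GLY A   5    %8.3f   0.000   0.000  1.00  0.00           C", d),
    "END", sep = "\n")
  expect_identical(nrow(build_calpha(parse_structure(mk2(6.9)), 7)$edges), 1L)
  expect_identical(nrow(build_calpha(parse_structure(mk2(7.1)), 7)$edges), 0L)
  expect_identical(nrow(build_calpha(parse_structure(mk2(7.0)), 7)$edges), 0L)
  # complete 3-nucleotide RNA -> 9 nodes (P, C4*, C2 each)
  rna <- build_calpha(parse_structure(make_nucleic("rna_hairpin", 3)), 7)
  expect_identical(nrow(rna$nodes), 9L)
  expect_identical(sort(unique(rna$nodes$node_kind)), sort(c("P", "C4*", "C2")))
  # 5'-truncated variant -> 8 nodes, skip counted in the log
  rna8 <- build_calpha(parse_structure(make_nucleic("rna_hairpin", 3, skip_5p = TRUE)), 7)
  expect_identical(nrow(rna8$nodes), 8L)
  expect_match(rna8$log, "skipped 1")
})

test_that("protein-RNA complexes get inter-molecular edges", {
  s <- parse_structure(make_nucleic("protein_rna_complex", 8))
  net <- build_calpha(s, 7)
  ci <- net$nodes$chain[match(net$edges$node_i, net$nodes$node_id)]
  cj <- net$nodes$chain[match(net$edges$node_j, net$nodes$node_id)]
  expect_gt(sum(ci != cj), 0)
  # inter-chain edges are labelled long-range
  expect_true(all(net$edges$long_range[ci != cj]))
})

test_that("C-alpha edge set is invariant under rigid motion", {
  txt <- make_peptide("two_chain_complex", 8)
  s <- parse_structure(txt)
  net1 <- build_calpha(s, 7)
  # rotate + translate all coordinates
  th <- 0.83
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% rot
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 11.3
  s2$atoms$y <- xyz[, 2] - 4.7
  s2$atoms$z <- xyz[, 3] + 0.9
  net2 <- build_calpha(s2, 7)
  expect_identical(paste(net1$edges$node_i, net1$edges$node_j),
                   paste(net2$edges$node_i, net2$edges$node_j))
})

test_that("all builders keep AM symmetric, zero-diagonal and edge-consistent", {
  fixtures <- list(
    build_aacen(parse_structure(make_peptide("helix_peptide", 10)),
                make_toy_energy_table(1)),
    build_nacen(parse_structure(make_peptide("two_chain_complex", 7)),
                make_toy_energy_table(2), weight_mode = "mass"),
    build_eacen(parse_structure(make_peptide("helix_peptide", 12)),
                make_toy_energy_table(3)),
    build_calpha(parse_structure(make_nucleic("protein_rna_complex", 6)), 7))
  for (net in fixtures) {
    expect_identical(net$AM, t(net$AM))
    expect_true(all(diag(net$AM) == 0))
    expect_identical(sum(net$AM != 0), 2L * nrow(net$edges))
    for (k in seq_len(nrow(net$edges))) {
      expect_identical(net$AM[net$edges$node_i[k], net$edges$node_j[k]],
                       net$edges$weight[k])
    }
    expect_false(anyDuplicated(paste(net$edges$node_i, net$edges$node_j)) > 0)
  }
})
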