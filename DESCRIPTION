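Package: aanet
Title: Construction and Analysis of Amino Acid Networks from Macromolecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained residue interaction networks from 3D
    structures in PDB format and analyses them at the node, edge and network
    level. Four network models are supported: the amino acid contact energy
    network (AACEN), whose edges are residue pairs with negative
    environment-dependent residue contact energy (ERCE); its node-weighted
    (NACEN) and edge-weighted (EACEN) extensions; and a C-alpha
    distance-threshold network that extends to protein-DNA/RNA complexes by
    representing each nucleotide with P, C4* and C2 nodes. Includes a
    backbone-dihedral secondary-structure classifier, a Shrake-Rupley solvent
    accessibility calculator, per-residue physicochemical node weights,
    node-weighted and edge-weighted centralities, deterministic exporters
    (edge list, node list, adjacency matrix, GraphML), synthetic structure
    generators for testing, and single-structure and batch command-line
    workflows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
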