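---
title: "Amino acid networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino acid networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aanet)
```

## The models

`aanet` represents a macromolecular structure as an undirected graph. For
proteins, one node per amino-acid residue; for DNA/RNA, three nodes per
nucleotide (the P, C4\* sugar and C2 base atoms), so that backbone, sugar
and base contacts are distinguishable at a coarse-grained level.

Edges come from one of two sources:

1. **Geometry only** (C-alpha model): an edge whenever two representative
   atoms are closer than a distance threshold. Simple, applicable to any
   complex, but blind to residue chemistry.
2. **Contact energy** (AACEN family): a residue pair within a candidate
   distance cutoff becomes an edge only when its environment-dependent
   residue contact energy (ERCE) is below a threshold (default 0, i.e.
   favourable). The ERCE alphabet has 60 letters — 20 residue types × 3
   secondary-structure states — so a leucine in a helix and the same
   leucine in a loop score differently. The strict inequality matters:
   a pair with e_ij exactly at the threshold is *not* an edge.

NACEN adds node weights to the AACEN topology; EACEN adds edge weights

\[
w_{ij} =
\begin{cases}
0.0001 & \text{if } |e_{ij}| = |e|_{min}\\[2pt]
\dfrac{|e_{ij}| - |e|_{min}}{|e|_{max} - |e|_{min}} & \text{otherwise}
\end{cases}
\]

with the extrema taken over the edges of the network at hand (the
normalisation is relative to the structure, not to a global constant: the
formula's purpose is to spread one network's couplings over (0, 1]).
Consequences we implement literally rather than "fix": an edge whose
\(|e|\) is only marginally above the minimum receives a weight *below*
0.0001 — the formula is printed that way and clamping would distort the
spacing of all other weights; and when every edge has the same energy the
second branch is 0/0, so the first branch applies to all edges (every edge
attains the minimum) and all weights are 0.0001.

### Assumptions

* The first model of a multi-model (NMR) entry represents the structure.
* The highest-occupancy alternate conformer represents each atom.
* Contact chemistry is captured by (type, secondary-structure) pairs — the
  premise of the quasichemical contact-energy approach. Everything finer
  (side-chain orientation, hydrogen bonds, electrostatics) is out of scope.
* Covalent neighbours are not "contacts": same-chain pairs with sequence
  separation < 2 are excluded from candidate contacts (configurable).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `d_cutoff` (energy models) | 8.0 | Å | C-alpha–C-alpha capture radius standard in residue-contact studies; large enough to include side-chain-mediated contacts, small enough to exclude second-shell pairs |
| `d_cutoff` (C-alpha model) | 7.0 | Å | the usual threshold in the distance-network literature |
| `e_thresh` | 0 | energy units of the table | edge iff the contact is favourable |
| `exclude_adjacent` | 2 | residues | removes covalent i, i±1 links |
| `lr_sep` | 12 | residues | sequence separation beyond which a same-chain contact is "long-range"; inter-chain edges are always long-range |
| `weight_mode` | polarity | — | NACEN node weights: `sas`, `mass`, `hydrophobicity`, `polarity`, or a custom file |
| probe radius | 1.4 | Å | water-sized probe for Shrake–Rupley accessibility |

Contact geometry for the energy models is C-alpha distance by default, with
a minimum-heavy-atom-distance mode (`atom_mode = "heavy"`) for users who
prefer an all-atom capture criterion.

## The energy table

The package treats the ERCE table as data, not code: any symmetric,
complete 60×60 TSV over the `RES_SS` alphabet loads via
`load_energy_table()`, is validated (symmetry to 1e-9; all 3600 entries
finite), and its provenance string is propagated into every run log. The
shipped default is a **synthetic baseline**: Miyazawa–Jernigan (1996)
contact energies expanded by the additive approximation
\(e_{ij} = (e_{ii}+e_{jj})/2\), mean-centred so that
better-than-average contacts are negative, and replicated across the three
secondary-structure states. It gives chemically sensible edge sets
(hydrophobic cores become densely connected) but it is *not*
environment-dependent within a residue pair; analyses that rely on the
environment splitting should supply a published ERCE table. All package
tests use small hand-built toy tables precisely so that no result depends
on the default's values.

## Secondary structure and node weights

No external assigner is assumed. A built-in backbone-dihedral classifier
labels each residue helix (φ ∈ (−145°, −10°), ψ ∈ (−90°, 45°)), strand
(φ < −45°, ψ > 90° or ψ < −120°, with the ±180° wrap folded into the
extended region) or coil, then reverts helix runs shorter than 4 and strand
runs shorter than 2 to coil — mimicking the minimal segment lengths of
DSSP's definitions. Termini, chain breaks (peptide bond > 2.5 Å) and
residues with missing backbone atoms default to coil. The classifier is
deterministic in the coordinates.

Node weights: mass (average residue mass, Da), hydrophobicity
(Kyte–Doolittle) and polarity (Grantham) are pure type lookups. Relative
solvent accessibility is computed structure-dependently: Shrake–Rupley with
a 1.4 Å probe and 120 deterministic spiral test points per atom, summed per
residue and divided by the Tien et al. (2013) theoretical maxima; values
are capped at 1.2 because exposed termini of small peptides can exceed the
tripeptide-based maximum. Weighted betweenness/closeness interpret node
weights through the edge-length transform \(l_{ij} = (w_i + w_j)/2\),
isolated in one function so an alternative transform can be swapped in; the
choice is recorded in each report's `conventions` field. Path-based
weighted metrics require strictly positive weights — the Kyte–Doolittle
scale spans negative values, so hydrophobicity weights must be shifted by
the user before weighted path metrics are meaningful; the package refuses
them with an explicit error rather than silently shifting.

## Metric conventions

* Betweenness and edge betweenness are reported unnormalised; closeness as
  (number of reachable nodes)/(sum of distances to them). Both conventions
  are stated in the output metadata. Rankings — the primary use of these
  centralities — are invariant to these choices within a connected
  component.
* Disconnected graphs: closeness and the per-node mean shortest-path
  distance are computed over reachable pairs only; L_net averages over
  connected pairs; the diameter is the largest finite eccentricity. An
  edgeless network has L_net = NA and diameter 0. Isolated nodes get
  closeness 0 and mean distance NA.
* Local clustering (transitivity) is 0 for nodes of degree < 2.
* EACEN path metrics use length 1/w ("strong links are short"); the
  alternative length = w is available (`eacen_length = "direct"`). Degree
  stays topological (edge count) in all models. A literal consequence of
  the weight floor: the minimum-|e| edge has length 1/0.0001 = 10⁴, so
  shortest paths avoid it, and when such an edge is a bridge the EACEN
  L_net and diameter are dominated by that length — interpret the weighted
  distances of sparsely connected EACENs accordingly.

## The synthetic structure generators

Test fixtures are generated, not stored: peptides are built residue by
residue from ideal bond lengths/angles at fixed dihedrals (helical
φ = −57°, ψ = −47°, or extended φ = ψ = 180°), with residue types cycling
through the 20 standard amino acids; nucleic chains place P/C4\*/C2 atoms
on a coarse helical trace with A-form-like rise and twist; complexes
translate a second chain into contact range. A seed controls optional
Gaussian coordinate jitter, and identical arguments yield byte-identical
PDB text.

The generators emulate what the builders consume — backbone geometry,
chain/residue bookkeeping, representative-atom placement, inter-chain
contacts — and deliberately **not** side-chain packing, realistic
nucleic-acid geometry, crystallographic artefacts or missing density.
Passing tests therefore demonstrate the correctness of parsing, secondary
structure assignment, edge rules, weighting and metrics, but say nothing
about how well any particular energy table ranks residues in real
structures; that depends on the table supplied.

## Numerical choices and degenerate inputs

* Energy-table symmetry tolerance 1e-9; sub-tolerance asymmetry is averaged
  away at load so lookups are exactly symmetric.
* Centralities are validated against a brute-force all-shortest-paths
  enumerator (independent Dijkstra with path counting) to 1e-9 —
  exhaustively over all labelled graphs on ≤ 5 nodes, over 300 random
  6-node graphs, and over 50 random graphs of up to 12 nodes: sizes chosen
  to keep the enumeration exact and the suite fast while covering every
  topology class that small graphs exhibit.
* Ties in shortest paths are handled by exact path counting on both routes;
  tied weighted distances are compared with an absolute epsilon of 1e-10 in
  the oracle.
* Zero amino acids → the energy builders raise an empty-network error;
  zero representable nodes → the C-alpha builder does. Missing nucleotide
  representative atoms are skipped and counted in the run log. A nucleotide
  contributes at most 3 nodes; intra-nucleotide node pairs are linked by
  distance like any others (the alternative — unconditional linking — is
  not used because it would invent edges at large rise distances).
* All exports are canonically sorted (nodes by chain, sequence position,
  insertion code, atom role; edges oriented and sorted in node order) and
  no output carries timestamps, so repeated runs are byte-identical.

## Known limitations

* PDB format only (no mmCIF); first NMR model only; no structure repair or
  hydrogen handling.
* The default energy table is a synthetic baseline (above); absolute edge
  sets will differ from analyses run with a published environment-dependent
  table, which is why the tests pin behaviour to toy tables and to analytic
  constants rather than to the default's edge sets.
* Node-weighted centrality definitions beyond the (w_i + w_j)/2 transform
  (e.g. endpoint-weighted betweenness variants) are not implemented.
* Networks are static: no trajectories, no perturbation analysis, no
  community detection.
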