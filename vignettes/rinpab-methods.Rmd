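---
title: "Clique co-membership as a predictor of mutation coupling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clique co-membership as a predictor of mutation coupling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinpab)
```

## The model

`rinpab` asks a structural question about a pair of mutation sites: *how
often, across the conformations a protein actually visits, are the two sites
locked into a triangle of mutually interacting residues?* The premise is that
coupling between mutations (thermodynamic non-additivity, ΔΔΔG ≠ 0) requires
a persistent three-body interaction motif, whereas pairs that merely touch,
or that interact only transiently, behave additively.

The pipeline has three layers.

**Residue interaction network.** Each conformer (a `Snapshot`) becomes an
unweighted simple graph: nodes are residues (conceptually placed at their
Cα atoms), and an edge connects two residues if *any* of six non-covalent
interaction detectors fires. The detectors and their default geometric
criteria are:

| type | criterion | cutoff (Å) | energy annotation (kJ/mol) |
|---|---|---|---|
| hydrogen bond | donor–acceptor heavy-atom distance | 3.5 | 115 / 40 / 17, tiered on distance |
| van der Waals | surface gap (center distance − Bondi radii) | 0.5 | 6.0 |
| disulfide | Cys SG–SG distance | 2.5 | 167.0 |
| ionic | mass centers of opposite charged groups | 4.0 | 20.0 |
| π-π stacking | aromatic ring geometric centers | 6.5 | 9.4 |
| π-cation | cationic-group center to ring center | 5.0 | 9.6 |

Parallel detections between one residue pair collapse to a single graph
edge; the per-interaction detail (type, distance, energy tier) is kept for
reporting. The energies are annotations only — every downstream graph
algorithm is purely topological, so they never influence communities or
P_ab. Isolated residues remain as nodes.

**3-clique communities.** A k-clique is a complete subgraph on k nodes; the
package uses k = 3 (triangles) by default. Two k-cliques are *adjacent* when
they share k − 1 nodes — for triangles, a common edge — and a community is
the union of a maximal chain of adjacent k-cliques (the clique percolation
method). Communities may overlap, and nodes in no triangle belong to no
community.

**The P_ab statistic.** For an ensemble of N snapshots, with C_ab(t) the
indicator that sites a and b share a 3-clique community in snapshot t,

$$P_{ab} = \frac{1}{N}\sum_{t=1}^{N} C_{ab}(t), \qquad
\hat{\mathrm{se}} = \sqrt{P_{ab}(1 - P_{ab})/N}.$$

The decision rule is boundary-inclusive: P_ab ≥ 0.1 → non-additive. The
binomial standard error is reported alongside (it is not part of the rule;
it exists so that synthetic-recovery experiments can state calibrated
bands). Note the estimator ignores autocorrelation between successive MD
frames, so `se` understates the true uncertainty on correlated
trajectories; a `stride` argument allows thinning.

## Tunable parameters

* `k` (default 3) and `threshold` (default 0.1) — the published operating
  point; both are exposed because the generalisation is free, but all
  validation here is at k = 3.
* `interaction_params()` — every cutoff above, the per-element van der
  Waals radii (Bondi values: C 1.70, N 1.55, O 1.52, S 1.80 Å), and
  `min_seq_separation` (default 1, i.e. only self-pairs are excluded;
  sequence-adjacent residues genuinely co-occur in published lysozyme
  cliques, so i/i+1 edges must be allowed).
* `same_triangle` — a stricter variant of C_ab requiring both sites in one
  and the same triangle rather than one percolation community. Off by
  default: community membership is the documented semantics; the strict
  variant is provided because the two readings differ exactly when a pair
  is linked through a chain of triangles, and it is always ≤ the default.

## Conventions the criteria do not fix

Several atom-typing choices are not determined by the distance criteria
alone; the package fixes them explicitly and they are configurable where
reasonable:

* Hydrogen bonds use heavy-atom donor–acceptor distance only — no
  explicit-hydrogen geometry, no angle term. Donors/acceptors are the
  standard chemical assignments (backbone N donates, backbone O/OXT
  accepts; Ser/Thr/Tyr hydroxyls both; Asn/Gln amides; Lys NZ, Arg NE/NH*,
  Trp NE1 donate; Asp/Glu carboxylates accept; His ring nitrogens both).
* Histidine is treated as cationic for ionic edges (`his_cationic`) and
  aromatic for π-π (`his_aromatic`), but never as the cation of a π-cation
  pair. These are fixed, documented conventions, not inferences.
* Tryptophan contributes both rings to π detection; the closest
  ring-center pair is used.
* Charged-group distances use *mass-weighted* centers; ring distances use
  unweighted geometric centers.
* Alternate locations resolve to the highest-occupancy record, ties to
  altloc `'A'`; waters/heteroatoms are dropped by default; hydrogens are
  parsed and flagged but ignored by the detectors.

One definitional point deserves emphasis: clique adjacency is *k − 1 shared
nodes* (the standard clique percolation definition). A literal "k − 1 edges
linking the two cliques" reading is ambiguous for k = 3 and does not
correspond to the named published method, so it is not implemented.

## The synthetic generator

Real validation data for P_ab would require ~100 ns of MD per variant
(ensembles of 10^4 snapshots); the package therefore ships a generator whose
ground truth is known *by construction*, and treats MD ensembles strictly as
input.

`make_structure()` places Cα atoms on an extended, helical or ring backbone
and adds the minimal atoms needed to realize each requested interaction:
every planted interaction satisfies its criterion with ≥ 0.2 Å margin, and
non-planted pairs miss their cutoffs by ≥ 0.5 Å where the backbone geometry
allows (a helix's adjacent Cα contacts are geometrically unavoidable and
are reported via the `unplanned_edges` attribute). Structures are
chemically minimal on purpose — the detectors read only distances and atom
typing, so correctness testing needs controlled geometry, not
stereochemistry.

`make_ensemble()` draws a Bernoulli(f) event per snapshot (seeded;
default anchor seed 20180510): in event snapshots a designated residue
triple is closed into a mutual-contact (disulfide) triangle held 5 Å off
the backbone plane; otherwise one contact atom is displaced a further 6 Å,
breaking the triangle while the remaining pair edge persists. Cα positions
receive Gaussian jitter (default σ = 0.1 Å), and contact atoms are
re-derived from the *jittered* Cα positions, so detection is immune to
jitter and the pipeline's P_ab equals the realized event fraction exactly —
the returned `events` attribute is a ground-truth ledger, which the test
suite asserts (including that broken snapshots contain no spurious event
triangle). What passing these tests shows is that the network → clique →
probability machinery is exact; what they deliberately do not show is
anything about force-field realism, frame autocorrelation, or how real
side-chain packing maps onto the six criteria.

`make_graph_ensemble()` provides the same event construction at the graph
level (Erdős–Rényi backgrounds), bypassing geometry for community-detection
tests.

## Numerical and implementation choices

* Residue identity is `chain:number` with author (PDB) numbering kept
  verbatim — site labels match the experimental literature (98, 152, …).
  Keys zero-pad the number so lexicographic order equals numeric order.
* Community output order is fully lexicographic on the sorted member
  lists; two overlapping communities can share their smallest member, so
  sorting by first member alone would not be deterministic.
* Clique enumeration delegates to `igraph`; percolation itself is a
  union-find over (k−1)-subset keys, checked in the tests against an
  independent brute-force oracle (enumerate all triples, build the
  triangle-overlap graph, take connected components).
* `ddg_sum` and `dddg` are single floating-point operations per row
  (bitwise-reproducible); the test suite checks the re-associated residual
  |ΔΔΔG + ΔΔG_i + ΔΔG_j − ΔΔG_ij| < 10⁻¹² rather than 0 because floating
  point addition is not associative.
* Pearson is the primary prediction-comparison statistic, with Spearman
  reported as a robustness column. No |ΔΔΔG| threshold is imposed on the
  thermodynamic side: the package reports magnitudes and leaves the
  labelling to P_ab, since the experimental tables mix units (kJ/mol and
  kcal/mol) and the statistic is unit-covariant.
* Degenerate inputs: empty snapshots and ensembles are errors; a pair
  absent from a snapshot names the offending model; residues without a Cα
  are flagged and warned about but kept; unknown elements are skipped by
  the van der Waals detector with a warning; incomplete aromatic rings are
  skipped with a warning.

## Validation problem sizes

The shipped tests and the acceptance script validate at sizes chosen to
exercise every code path while staying comfortably reproducible on a
laptop: brute-force clique-percolation equivalence on 200 random graphs of
up to 20 nodes at edge densities 0.2–0.5; detector-vs-naive-scan
equivalence on ~50-residue random atom clouds; P_ab recovery on
1000-snapshot synthetic ensembles at event fractions 0.05, 0.3 and 0.7
(3σ binomial bands); and the published 13-pair lysozyme tables for the
classification and correlation endpoints.

## Known limitations

* The six detectors approximate a full interaction-network generator;
  exact atom-typing of established tools (e.g. angle-aware hydrogen bonds)
  is out of scope, so absolute edge sets on real proteins will differ in
  detail even where the distance criteria match.
* P_ab values for real variants depend on the quality and length of the
  input ensemble; the package computes the statistic but cannot substitute
  for adequate sampling, and reproducing published per-variant P_ab tables
  requires the original ~100 ns trajectories.
* The classifier is known to under-call coupling for proteins with sparse
  networks (few triangles), and a third mutation can shift a pair's P_ab
  substantially — the statistic describes a structural ensemble, not a
  universal property of the pair.
* The binomial `se` assumes independent snapshots; MD frames are
  autocorrelated, so treat it as a lower bound (use `stride`, or block
  methods outside the package, for honest uncertainty).
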