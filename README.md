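# rinpab

Topology-based prediction of **double-site mutation non-additivity** from
residue interaction networks of protein conformational ensembles.

## The problem

When two stabilising (or destabilising) mutations are combined, the free
energy change of the double mutant often equals the sum of the single-mutant
changes — the mutations are *additive*. Pairs that deviate from the sum are
*coupled* (non-additive), and knowing which pairs will couple is central to
multi-site enzyme design. For a double mutation at sites *i* and *j* with
single-mutant unfolding free-energy changes ΔΔG_i and ΔΔG_j and double-mutant
change ΔΔG_ij, the additivity deviation is

```
ΔΔG_sum  = ΔΔG_i + ΔΔG_j
ΔΔΔG_ij  = ΔΔG_ij − ΔΔG_sum
```

ΔΔΔG ≈ 0 means additive; large |ΔΔΔG| means the sites interact.

`rinpab` implements a purely topological predictor of this coupling. For each
conformer of an ensemble (e.g. snapshots of an MD trajectory, read from a
multi-model PDB) it:

1. builds the **residue interaction network** (RIN): residues are nodes,
   edges are detected non-covalent interactions of six types — hydrogen
   bonds (donor–acceptor heavy atoms ≤ 3.5 Å), van der Waals contacts
   (surface gap ≤ 0.5 Å), disulfide bonds (SG–SG ≤ 2.5 Å), ionic
   interactions (charged-group mass centers ≤ 4.0 Å), π-π stacking (ring
   centers ≤ 6.5 Å) and π-cation (≤ 5.0 Å);
2. finds the overlapping **3-clique (clique percolation) communities** of
   that network: triangles of mutually interacting residues, merged whenever
   two triangles share an edge;
3. evaluates the indicator C_ab(t) = 1 if sites *a* and *b* fall in the same
   3-clique community in snapshot *t*.

The clique co-membership probability over an ensemble of N snapshots,

```
P_ab = (1/N) Σ_t C_ab(t)
```

is the predictor: **P_ab ≥ 0.1 classifies the pair as non-additive**. On the
published T4 phage lysozyme benchmark of 13 double mutations this rule
isolates exactly the two experimentally coupled pairs, (117, 132) and
(98, 152), from the eleven additive ones.

## Worked example

A synthetic 4-residue ensemble in which residues {2, 3, 4} are closed into a
mutual-contact triangle in a controlled 30% of 500 snapshots:

```r
library(rinpab)

spec <- toy_spec(4, "ring",
                 planted = list(list(pair = c(1, 2), itype = "hbond")),
                 event = list(triple = c(2, 3, 4), f = 0.3), seed = 20180510)
e <- make_ensemble(spec, 500)
pab_table(e, list(c("A:2", "A:4"), c("A:1", "A:3")))
#> P_ab over 500 snapshots (k = 3, threshold = 0.1):
#>    a   b  p_ab n_events   n     se classification
#>  A:2 A:4 0.294      147 500 0.0204   non_additive
#>  A:1 A:3 0.000        0 500 0.0000       additive
```

The event pair (2, 4) recovers the planted co-membership fraction (0.294 vs
the realized 147/500, exactly; near the target f = 0.3 with binomial standard
error 0.02) and is called non-additive; the control pair (1, 3) never shares
a clique and is additive. The same classification applied to the published
wild-type lysozyme P_ab values:

```r
tab <- read.csv(system.file("extdata", "t4l_pab_models.csv", package = "rinpab"),
                comment.char = "#")
table(classify_additivity(tab$WT, threshold = 0.1))
#>     additive non_additive
#>           11            2
```

And the thermodynamic side — the observed ΔΔΔG of the 13 lysozyme double
mutations against a structure-based free-energy predictor correlates only
weakly, which is what motivates a topological classifier:

```r
ddg <- read_mutation_table(system.file("extdata", "t4l_dddg_maestro.csv",
                                       package = "rinpab"))
compare_predictions(ddg$observed, ddg$predicted)
#> $pearson   0.329
#> $spearman -0.215
#> $n         13
```

A command-line wrapper with subcommands (`build-network`, `cliques`, `pab`,
`dddg`, `distance`, `compare`, `synth`) is installed at
`system.file("cli", "rinpab", package = "rinpab")`:

```sh
rinpab pab ensemble.pdb --pair A:98 A:152 --k 3 --threshold 0.1 --out pab.json
```

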