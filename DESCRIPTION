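Package: rinpab
Title: Residue Interaction Networks, 3-Clique Communities, and Mutation
    Additivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds residue interaction networks from protein conformational
    ensembles (multi-model PDB), detects six non-covalent interaction types
    (hydrogen bonds, van der Waals contacts, disulfide bonds, ionic
    interactions, pi-pi stacking, pi-cation), finds overlapping k-clique
    (clique percolation) communities, and computes the ensemble probability
    P_ab that two mutation sites co-occur in a 3-clique community, a
    topological predictor of double-site mutation non-additivity. Also
    provides the thermodynamic additivity statistics (delta-delta-delta-G)
    for double-mutant tables and a synthetic structure/ensemble generator
    with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
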