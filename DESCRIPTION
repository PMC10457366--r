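Package: plmgraph
Title: Protein Language Model Features for Residue-Level 3D Protein Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds residue-level 3D protein graphs (k-nearest-neighbour,
    radius and fully-connected connectivity) from PDB structures, reconciles
    structure-derived sequences with full-length FASTA sequences by global
    pairwise alignment, and injects per-residue sequence-embedding matrices
    from pluggable providers into graph node features. Includes a minimal
    E(3)-invariant message-passing network, a synthetic backbone generator and
    the absolute/relative position-recovery toy benchmarks that demonstrate
    why geometry-only node features are position-blind, together with the
    evaluation-metric suite used in structure-based model assessment: per-target
    and pooled ranking correlations, first rank loss, AUROC, Kabsch
    superposition and the fixed-receptor docking RMSD family with interface
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
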