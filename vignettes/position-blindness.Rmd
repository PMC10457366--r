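---
title: "Position blindness in geometric protein graphs, and sequence features as the remedy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position blindness in geometric protein graphs, and sequence features as the remedy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plmgraph)
```

## The problem

Geometric graph neural networks consume a protein as a residue-level 3D
graph: N nodes at the Calpha coordinates `x` (N x 3, Angstrom), invariant
scalar features `h` (N x psi_h, e.g. one-hot residue classes), and edges
built from geometry alone. Because the messages passed along edges depend
only on node features and inter-node distances, two residues with similar
features and isometric neighbourhoods are indistinguishable to such a
network — in particular, nothing in the input says *where along the chain*
a residue sits. Per-residue representations from a protein language model
(PLM), which are strongly position- and context-aware, can be injected as
node features to supply exactly that missing information.

This package implements the full pipeline around that idea at desk scale:
structure and sequence I/O, the three standard graph connectivities,
sequence–structure reconciliation, a pluggable embedding provider with
three integration modes, a minimal invariant message-passing network, two
diagnostic "position recovery" benchmarks, and the evaluation metrics used
in structure-based assessment tasks (model quality assessment, rigid
docking, interface prediction, affinity regression).

## Graph construction

`build_graph()` supports the three standard connectivity schemes:

* **KNN** — each node receives directed edges to its K nearest neighbours
  (default K = 10). Edges are *not* symmetrised by default: "linked to K
  nearest neighbours" is a statement about out-edges, and in-degree
  asymmetry near chain termini is real signal. `symmetrize = TRUE` gives
  the union closure. Distance ties break to the smaller node index so
  construction is deterministic.
* **r-ball** — all pairs strictly closer than a cutoff (default 8
  Angstrom), stored in both directions. The strict `<` matches the
  convention used for interface extraction, keeping one comparison rule
  package-wide.
* **FC** — all N(N−1) ordered pairs.

Edge sets are functions of pairwise distances only, hence invariant under
any rigid motion or reflection of the coordinates; the test suite asserts
this over random transforms.

## Sequence–structure reconciliation

Deposited structures are usually incomplete, so the structure-derived
sequence is a fragment of the full FASTA sequence. `reconcile()` exposes
both standard treatments:

* **fragment** (default) — embed the fragmentary sequence itself; the
  mapping is the identity on structure positions. Simple, and adequate
  when unresolved stretches are short.
* **align** — globally align the full sequence to the fragment
  (Needleman–Wunsch, linear gaps, defaults match = 1, mismatch = −1,
  gap = −2) and abandon residues absent from the structure. Mismatch
  columns are *kept* (they are sequence variants, not absences).

The aligner is written in-package because the mapping contract requires a
deterministic traceback (diagonal over up over left among co-optimal
paths); its scores are verified in the tests against exhaustive
enumeration over all alignments and against an independent library
aligner. The scoring triple is deliberately the simplest one whose
optimum is oracle-checkable; alignment here only needs to recover
*which* residues are missing, not model evolutionary substitution rates.

## Embeddings and integration

An `EmbeddingProvider` maps a sequence to an N x psi_PLM matrix, one row
per residue (default width 1280, the width of a commonly used PLM). The
packaged `mock_provider()` hashes (seed, residue letter, position) into a
seeded pseudo-random row: deterministic, position-aware, and free of any
model weights, so every pipeline is runnable and testable offline. A real
PLM plugs in behind the same interface; nothing downstream changes.

`integrate_features()` implements the three integration modes: `replace`
(the default for residue-level graphs — the embedding becomes the node
feature), `concat`, and `add` (which requires psi_h = psi_PLM).
`project_embedding()` carries full-sequence embeddings onto structure
residues through a reconciliation mapping. Multi-chain complexes are
embedded per chain and concatenated node-wise, since sequence models are
trained on single chains.

## The reference network

`mpnn()` is a deliberately minimal invariant message-passing network: the
message on edge (i, j) is a linear map of the source features and a radial
basis expansion of the edge distance; the receiving node's features enter
through a ReLU update; the head (masked softmax classification or scalar
regression) reads the last hidden layer concatenated with the raw input
features. Three design choices deserve comment:

* **Scalar invariance only.** Distances are the sole geometric input — no
  vector channels, no spherical harmonics. The position-blindness
  conclusions depend on invariance, not on any particular backbone, so
  the reference model is the smallest member of the invariant family.
* **Linear-in-source messages.** Because the message is linear in
  (h_source, rbf(d)), aggregation commutes with the weight multiply and
  each layer costs node-sized rather than edge-sized matrix products.
  The expressiveness lost relative to an edge-MLP does not affect any
  conclusion drawn here: the informed conditions are solvable by
  construction and the blind conditions fail for information-theoretic
  reasons, not capacity ones.
* **Input-skip head.** The head sees the raw features alongside the last
  hidden layer, so tasks solvable directly from the inputs are learnable
  without relying on identity information surviving the hidden
  bottleneck.
* **Target standardisation.** Regression targets are standardised for
  optimisation and unscaled at prediction; reported RMSEs are on the raw
  label scale.

Training is full-batch Adam (default 150 epochs, learning rate 0.02, seed
in the config), making every fit bit-reproducible from (data, config).
Classification masks classes beyond each chain's length out of both loss
and argmax, which is our reading of "predict the index from 1 to N" under
variable N.

## The synthetic cohort

`gen_toy_dataset()` emulates single-domain backbones as self-avoiding 3D
random walks: consecutive Calpha spacing fixed at 3.8 Angstrom (the
trans-peptide standard), turning angles bounded at 120 degrees,
non-consecutive residues rejected below 3.0 Angstrom, residue letters
uniform over the 20 standard amino acids. The default cohort is 300
chains, lengths uniform on [30, 80], split 240/30/30 — sized so that a
full benchmark sweep runs in minutes on one CPU while chance APR accuracy
(E[1/N] ≈ 2%) stays well separated from the informed regime.

What the generator does *not* emulate: secondary structure, compact
globular packing, realistic residue composition or contact order, and any
correlation between sequence and geometry. Passing benchmarks here
therefore demonstrate properties of the *pipeline and the information
content of its features* — position blindness is an information argument
that holds regardless — but they say nothing about absolute accuracies on
real PDB-derived data, and numbers from the full-scale published setting
are not reproduced at this scale.

## The position-recovery benchmarks

Two label sets probe whether a network can recover sequence position from
structure:

* **APR** (absolute position recognition): classify each residue's
  1-based index; metric accuracy; chance level E[1/N].
* **RPE** (relative position estimation): regress each residue's minimum
  distance to the two chain ends, `min(i−1, n−i)`; metric RMSE. We count
  this distance in residue steps (the task probes sequence, not
  geometry; the published description does not fix a unit) and the first
  residue's distance to its own end is 0, making the boundary canonical.

`run_experiment()` sweeps a feature regime over the cohort:

* `structure_only` — one-hot residue class (21-dim). Position can only
  enter through geometry.
* `with_index` — the informed control: one-hot class, one-hot absolute
  index, and three positional scalars (i/n and the distances to the two
  termini in residue decades). A note on this choice: a *normalised*
  index i/n alone cannot determine either label, because both APR's
  target i and RPE's target min(i−1, n−i) also require n, which a local
  message-passing network cannot recover; the control is meant to
  demonstrate that the tasks are solvable *when position is an input*,
  so the input must actually determine the labels. The decade scaling of
  the termini distances keeps the required head weights near unit size,
  which full-batch Adam reaches within the default epoch budget.
* `with_embedding` — provider embeddings in `replace` mode (mock, width
  32 by default at this scale).

The signature result, recomputed by `scripts/acceptance.R` and asserted
by the test suite: geometry-only features leave APR accuracy at chance
level (within 2x of E[1/N]) and RPE at the accuracy of a constant
predictor, while explicit positional inputs take APR accuracy above 0.90
and RPE RMSE below half a residue step. The small excess of
structure-only APR accuracy over exact chance is itself informative: on
30–80-residue chains the two termini are a few percent of all residues
and are geometrically detectable (sparser neighbourhoods), though the
walk's symmetry prevents telling the N- from the C-terminus.

The mock-embedding regime is instructive in both directions: it rescues
APR (each (letter, position) pair maps to a fixed, position-aware
vector), but not RPE — a per-residue embedding of position i is the same
in a 30-chain and an 80-chain, while the RPE label min(i−1, n−i) also
depends on n, which no per-node feature supplies. Sequence-aware
features restore *absolute* position directly; relative-to-end
information additionally needs chain-level context.

## Evaluation metrics

The `metrics` functions cover the downstream assessment suites:
per-target ("mean") versus pooled ("global") Spearman/Pearson/Kendall
correlations — the per-target-average versus pooled-rows semantics
follows the established model-quality-assessment convention; Kendall is
the tie-corrected tau-b; zero-variance targets contribute 0 with a
warning rather than NaN so aggregation stays deterministic. First rank
loss is the per-target gap between the best model's true score and the
true score of the predicted-top model (prediction ties to the smaller
model id). AUROC is the Mann–Whitney pair-counting definition with ties
at one half. `pk_from_affinity()` converts Molar affinities to
pK = −log10 K.

For rigid docking, `docking_rmsds()` defaults to the **fixed-receptor**
convention: predicted and true complexes are compared in the frame where
the receptors coincide, with no superposition of the compared point sets;
ligand, complex, and interface RMSDs are reported, with interface
residues extracted from the ground-truth complex at a strict 8 Angstrom
Calpha–Calpha cutoff (the cutoff is exposed; whether the published
threshold is Calpha- or any-atom-based is unstated). The alternative
**kabsch** convention superposes each compared set first and is always at
most the fixed-receptor value, a relation the tests assert. `kabsch()`
itself is the SVD solution with the rotation forced proper (det = +1);
collinear inputs warn but still return a solution.

## Degenerate inputs and numerical choices

Graphs require N ≥ 2 finite coordinates; `rball` uses strict `<`;
KNN ties break to the smaller index. Alignment requires non-empty
sequences. AUROC requires both classes. Correlations require 2+ models
per target (singletons are excluded from the mean with a warning).
Training raises an explicit divergence error, naming the epoch, on a
non-finite loss. Parsing keeps the highest-occupancy altloc (ties to the
alphabetically first id), reads MODEL 1 by default (multi-model NMR
files would otherwise duplicate residues), drops residues without a
Calpha with a warning, and ignores HETATM except selenomethionine, which
becomes residue class "X". Hetero-residues inside chains are excluded
from N — a choice, flagged here, that the published setting leaves open.

## Worked example

```{r example, eval = FALSE}
ds <- gen_toy_dataset(seed = 1)          # 300 chains, 240/30/30
blind <- run_experiment(ds, "apr", feature_mode = "structure_only",
                        n_runs = 3, seed = 1)
informed <- run_experiment(ds, "apr", feature_mode = "with_index",
                           n_runs = 3, seed = 1)
blind; informed; chance_accuracy(ds)
```

## Limitations

The reference network is intentionally small and CPU-bound; it is a
vehicle for the information-content experiments, not a competitive
backbone, and published full-scale benchmark numbers (which require
external datasets, pretrained PLM weights and GPU training) are out of
scope. The mock provider encodes position by construction; it
demonstrates the plumbing and the rescue mechanism, not the quality of
any real language model. mmCIF input, atom-level graphs, and affine gap
penalties are not implemented.
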