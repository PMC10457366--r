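# plmgraph

Residue-level 3D protein graphs with protein-language-model node features,
plus the position-recovery benchmarks and evaluation metrics for
structure-based model assessment.

## The problem

Geometric graph neural networks represent a protein as a graph G = (V, E):
N residue nodes at Calpha coordinates **x** ∈ R^(N×3) with invariant scalar
features **h** ∈ R^(N×ψ_h), connected by K-nearest-neighbour (K = 10),
radius (r < 8 Å) or fully-connected schemes. Since messages depend only on
node features and inter-node distances, such networks are *position-blind*:
no input distinguishes residue 12 from residue 120 if their neighbourhoods
are isometric. Per-residue embeddings **h′** ∈ R^(N×ψ_PLM) from a protein
language model (ψ_PLM = 1280 for the usual reference model) carry exactly
the missing sequential information and can be injected as node features —
replacing **h** (the residue-level default), concatenated, or added.

`plmgraph` implements that pipeline end to end, offline and at desk scale:

- **structure_io** — PDB → ordered per-chain Calpha records (altloc by
  occupancy, MODEL selection, MSE → "X", missing-Calpha residues dropped);
  FASTA in/out.
- **seq_struct_align** — Needleman–Wunsch global alignment with a
  deterministic traceback, and both mismatch strategies for incomplete
  structures: embed the fragment (default) or align-and-abandon.
- **graph_build** — knn / rball / fc connectivity, deterministic tie
  rules, rigid-motion-invariant edge sets.
- **embedding** — pluggable providers behind one interface; a
  deterministic mock provider (no weights needed) plus
  replace/concat/add integration and full-sequence → structure
  projection.
- **mpnn** — a minimal E(3)-invariant message-passing network (classify /
  regress heads, full-batch Adam, bit-reproducible).
- **toy_tasks** — synthetic self-avoiding backbones (3.8 Å spacing) and
  the APR / RPE position-recovery benchmarks.
- **metrics** — mean/global Spearman–Pearson–Kendall (tau-b), first rank
  loss, AUROC, pK = −log10 K, Kabsch superposition, interface extraction
  (strict < 8 Å) and the fixed-receptor docking RMSD family.

## Worked example

```r
library(plmgraph)

ds <- gen_toy_dataset(seed = 1)   # 300 chains, lengths 30-80, 240/30/30

blind    <- run_experiment(ds, "apr", feature_mode = "structure_only",
                           n_runs = 3, seed = 1)
informed <- run_experiment(ds, "apr", feature_mode = "with_index",
                           n_runs = 3, seed = 1)
blind
#> task_result: APR / knn / structure_only
#>   accuracy = 0.0338 +/- 0.0061 over 3 runs
#>   chance accuracy (E[1/N]): 0.0191
informed
#> task_result: APR / knn / with_index
#>   accuracy = 1.0000 +/- 0.0000 over 3 runs
#>   chance accuracy (E[1/N]): 0.0191
```

Reading: with geometry-only node features the network classifies residue
positions at essentially chance level (0.034 vs E[1/N] = 0.019 — the small
excess is terminal residues, which are geometrically detectable); the same
network with explicit positional inputs solves the task outright. The
relative-position regression behaves the same way (RMSE ≈ 9.6 residue
steps blind vs 0.24 informed). That gap is the whole argument for
injecting sequence-aware per-residue features into geometric graphs.

The embedding pipeline on a real structure:

```r
mod  <- read_structure("protein.pdb")
frag <- derive_sequence(mod, "A")
full <- read_fasta("protein.fasta")[[1]]
mp   <- reconcile(full, frag, mode = "align")   # drop unresolved residues
emb  <- project_embedding(mock_provider(width = 1280)$embed(full), mp)
g    <- build_graph(chain_coords(mod, "A"), "knn", k = 10)
g    <- attach_features(g, integrate_features(residue_onehot(frag$seq),
                                              emb, mode = "replace"))
```

A command-line wrapper over the same functions ships at
`inst/cli/plmgraph.R` (subcommands: parse, align, graph, embed, featurize,
train, toy, eval-mqa, eval-dock); every run writes a JSON manifest that
`rerun_manifest()` replays bitwise.

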