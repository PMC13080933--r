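# pocketformer

A dual-track graph transformer for protein pocket–ligand modelling in pure
R: virtual screening, target fishing, and docking with pose ranking, plus
the joint training objectives that tie the three together and a seeded
synthetic complex generator that makes the whole stack testable on one CPU
in minutes.

## Who this is for

Method developers and students in structure-based drug discovery who want
a fully inspectable, desk-scale reference implementation of the
"pair-track transformer + contrastive/matching/docking multi-task
training" family of interaction models — every forward pass, every
gradient, every metric is plain R that can be read, stepped through and
tested, with no GPU or external downloads.

## The model

Pockets and molecules are typed 3-D atom graphs.  The encoder maintains
two coupled tracks:

* atom representations `a_i` (initialised from the atom type alone), and
* a pair representation `q_ij` with one channel per attention head,
  initialised from a Gaussian radial-basis expansion of squared
  inter-atomic distances plus bond-type embeddings:
  `q⁰_ij = Linear(exp(−γ_g‖x_i−x_j‖²)) + BondEmbed(b_ij)`.

Each transformer block uses the pair track as a per-head attention bias,

    Attn(Q_i, K_j, V_j) = softmax( Q_i·K_j / √(d/H) + q_ij ) V_j ,

and feeds the raw logits back, `q_ij ← q_ij + Q_i·K_j/√(d/H)`.  Since
geometry only enters through distances, every internal quantity is
invariant to rigid motion.  An equivariant head predicts coordinate
updates for docking,

    x̂_i = x_i + (1/n) Σ_j (x_i − x_j) c_ij ,   c_ij = ReLU((q^L−q⁰)U)W ,

and training combines four losses: bidirectional InfoNCE between pocket
and molecule CLS tokens, a matched/unmatched classifier on the ENCODE
token with hard-negative mining, a Huber loss on intra-ligand distances,
and an MSE loss on ligand coordinates.  See the methods vignette
(`vignettes/pocketformer-methods.Rmd`) for the full account.

## Worked example

Generate a small synthetic benchmark, train the docking objective, and
dock a held-in complex from a perturbed start:

```r
library(pocketformer)

spec  <- synthetic_spec(seed = 1)                   # 48-atom pocket, 12-atom ligand
pairs <- lapply(1:8, function(i) generate_complex(spec, i))

cfg   <- desk_train_config("docking", total_steps = 300L, seed = 1)
out   <- train(new_model(cfg$backbone, seed = 1), pairs, cfg)

start <- docking_start_pose(pairs[[1]], cfg)        # fixed perturbed start
res   <- dock(out$model, pairs[[1]], init_coords = start, recycles = 2)
res
#> <pose_result: score=-0.2393, RMSD=0.358 A, 3 refinement round(s)>
rmsd(start, pairs[[1]]$true_ligand_coords)
#> [1] 2.346689
```

The ligand starts 2.35 Å from its true pose; three rounds of refinement
bring it to 0.36 Å.  The printed `score` is the affinity ranking score
(arbitrary units, higher is better) used by `rank_poses()`: its
self-consistency term penalises poses the model would move a lot, so
near-native poses score high.

Screening uses the separate encoders and the standard early-recognition
metrics:

```r
lib <- read_pairs("library.jsonl")                  # from generate_dataset()
tab <- screen_library(model, lib[[1]]$pocket,
                      lapply(lib, `[[`, "molecule"),
                      labels = vapply(lib, `[[`, 1L, "match_label"))
auroc(tab$score, tab$label); bedroc(tab$score, tab$label, alpha = 80.5)
```

A thin command-line front end with `generate-data`, `train`, `screen`,
`fish`, `dock` and `evaluate` subcommands lives in
`inst/scripts/pocketformer.R`.

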