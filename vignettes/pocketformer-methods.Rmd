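---
title: "pocketformer: model, objectives and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pocketformer: model, objectives and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketformer)
```

## The problem

Scoring protein–ligand interactions underlies three everyday tasks in
structure-based drug discovery: *virtual screening* (rank a molecule library
against one binding pocket), *target fishing* (rank candidate pockets for
one molecule) and *docking* (predict the bound ligand pose and rank
candidate poses).  pocketformer implements a single dual-track graph
transformer that serves all three, together with the joint training
objectives that wire them up and a seeded synthetic complex generator that
makes every component testable on a desk machine.

## Model

### Inputs

A pocket or molecule is an `atom_graph`: atom types from a fixed
element-based vocabulary, Cartesian coordinates in Angstrom, and (for
molecules) chemical bonds.  Hydrogens are dropped on input — their
positions are rarely resolved experimentally and their omission halves the
quadratic pair cost.  Pockets are extracted from PDB structures at
residue granularity: a residue is kept whole if any heavy atom lies within
the contact radius (default 5 A) of the ligand, and complexes whose pocket
has fewer than five such residues are rejected by `validate_complex()`.

Virtual tokens are extra atoms placed at the entity centroid: a CLS token
summarises a graph for the contrastive heads, an ENCODE token carries
cross-entity context in the joint pass.  They carry no bonds; their
"connection to all atoms" exists only through the fully connected pair
representation.

### Dual-track encoder

The encoder maintains two coupled representations:

* **atom track** `a_i` (one d-vector per atom), initialised purely from the
  atom type via an embedding table — hence invariant to rigid motion;
* **pair track** `q_ij` (one channel per attention head), initialised as
  `Linear(RBF(|x_i − x_j|^2)) + BondEmbed(bond(i, j))`.

The radial-basis bank uses G = 16 Gaussian kernels `exp(−γ d²)` with γ
log-spaced on [0.01, 10] A⁻² — the widest kernel still discriminates at
~10 A separation, the narrowest at covalent range — followed by a learned
linear map onto the H pair channels.  The bank is fixed rather than
learned; capacity sits in the projection.  The no-bond embedding is pinned
to zero so that bonded and unbonded pairs at equal distance differ exactly
by the bond embedding.

Each of the L transformer blocks performs

1. pair-biased multi-head attention: per head,
   `logit_ij = (Q_i · K_j)/√(d/H) + q_ij[h]`, softmax, value aggregation,
   output projection, residual, layer norm;
2. a feed-forward block (ReLU) with residual and layer norm;
3. the pair update `q_ij[h] += (Q_i · K_j)/√(d/H)` using the same raw
   (pre-softmax, pre-bias) logits.

Both equations read d as the per-head dimension so they share one scaling.
A block consumes the incoming pair tensor as attention bias and emits the
updated one; with one scalar bias per head, H pair channels is the only
dimensionality consistent with both roles without extra projections.

Because every geometric quantity enters through pairwise distances, all
internal representations are invariant to global rotation and translation;
the test suite asserts this to 1e-4 over random rigid transforms, and
exactness is limited only by floating-point summation.

### Heads

* **Coordinate head** (docking):
  `c_ij = ReLU((q^L_ij − q^0_ij) U) W` is a scalar per ordered pair, and
  movable (ligand) atoms update as
  `x̂_i = x_i + (1/n) Σ_j (x_i − x_j) c_ij` over all real atoms of the
  joint context.  Differences of invariant features times difference
  vectors make the head SE(3)-equivariant by construction.  The output
  layer W starts at zero, so an untrained head is the identity on
  coordinates.  The pair-difference `q^L − q^0` focuses the head on what
  the network added on top of raw geometry.
* **Distance head**: a two-layer MLP on the symmetrised final pair
  features with a softplus output; symmetric, non-negative, zero diagonal.
  It is exposed for docking-style analyses but is not supervised by the
  four pre-training losses.
* **Projection heads**: linear maps g_P, g_M to a k = 128-dimensional
  space, L2-normalised, with similarity the dot product (a cosine).  The
  temperature is parameterised as `exp(log τ)` with τ₀ = 0.07, the
  standard contrastive convention.
* **Matching classifier**: a linear 2-class readout on the ENCODE-token
  embedding of a joint pass.
* **Docking score**: a small MLP applied to the pocket–ligand cross block
  of `q^L`, averaged over cross pairs.  An earlier design — a linear map on
  mean-pooled atom representations — was measurably insensitive to pose:
  pooling over ~60 atoms washed out the pose signal (pooled features moved
  by ~2% of their spread between native and 6-A-displaced poses, and a
  trained readout never exceeded chance at ranking).  The cross-pair
  track is where relative geometry lives, and reading it directly makes
  the score pose-sensitive; this is the package's deliberate deviation
  from the simpler pooled readout.

### Modes

The same parameter set runs in three modes: pocket-only, molecule-only
(separate passes for the contrastive objective and screening) and joint
(pocket + molecule atoms concatenated into one fully connected set with a
single pair tensor, no cross-entity bonds) for matching, docking and
scoring.  Sharing one backbone keeps the desk-scale parameter count small;
nothing in the architecture requires separate weights, and the separate
*passes* preserve the independence properties the objectives rely on
(e.g. contrastive similarity is invariant to independent rigid motions of
pocket and molecule).

## Training objectives

The total loss is the unit-weight sum of four components.

* **Contrastive** (`l_pmc`): InfoNCE over the batch in both directions
  (pocket→molecule and molecule→pocket softmax at temperature τ),
  cross-entropy against the diagonal, halved.  With uniform similarities it
  equals ln N exactly; with N = 1 it is 0.
* **Matching** (`l_pmm`): binary cross-entropy of the ENCODE-token
  classifier over positives plus hard negatives.  For each pocket one
  deceptive molecule (and symmetrically one deceptive pocket per molecule)
  is drawn with probability proportional to the softmax of off-diagonal
  similarities from the contrastive stage; an argmax variant picks the
  single worst offender.  The batch is the N positives plus the 2N mined
  negatives.  Mined molecules are recentred at the location of the target
  pocket's own ligand so that the classifier sees geometrically plausible
  but chemically wrong pairings.
* **Intra-molecular** (`l_intra`): mean Huber penalty (δ = 1 A, the scale
  of bond-length errors) on deviations of all intra-ligand pairwise
  distances from the true pose — keeps predicted conformations internally
  consistent while tolerating occasional large deviations from flexible
  parts.
* **Inter-molecular** (`l_inter`): mean squared coordinate deviation per
  ligand atom (A²) in the pocket frame — anchors the pose.

A step runs one pocket and one molecule pass per pair (contrastive), joint
passes on positives and mined negatives (matching), and joint passes with
the coordinate head (docking).  The docking pass starts the ligand from a
*fixed per-complex perturbed pose* (a rigid displacement at an RMSD drawn
once per complex from [1, 5] A) rather than from the true pose — a head
trained from the truth would simply learn the identity — and rather than a
freshly resampled perturbation each step, which defines a much harder
pose-generalisation task than desk-scale budgets support and does not
match practice: docking fine-tuning conventionally gives each complex one
starting conformation.  When refinement recycles are enabled, every round
of the trajectory is supervised, with gradients stopped between rounds
(each round treats its input pose as data), so that inference-time
iteration operates in-distribution.

Optimisation is AdamW (decoupled weight decay 0.05, skipping normalisation
gains, biases and τ) under a schedule that ramps linearly from 0 to the
peak over the warm-up and cosine-anneals to the minimum exactly at the
final step.  The reference schedule is a 1000-step warm-up with peak 1e-4
and minimum 5e-6.  Desk-scale toy runs (a few hundred steps) compress the
warm-up to 50 steps and raise the peak (1e-3; 2e-2 for docking-only runs,
whose gradients pass through a zero-initialised output layer and need
larger steps to converge within the budget).  Gradients are clipped to
global norm 1.0: without clipping, docking-only runs at the higher peak
rate were stable for some seeds and oscillated for others; with clipping
all tested seeds converge.

### Pose-ranking fine-tuning

None of the four losses supervise the docking score, so pose ranking is
trained separately by `fit_pose_ranker()`: per step one complex is drawn,
the native pose is scored alongside decoys at controlled RMSD, and the
softmax cross-entropy over the pose list (native as target) is minimised.
The listwise form matters: scores only ever need to be compared within one
complex, and a pointwise native-vs-decoy logistic loss spent its capacity
modelling cross-complex score offsets instead of within-complex contrasts
(it never exceeded chance in our runs).  Fine-tuning starts from a
docking-trained backbone, whose pair track already encodes where the
ligand belongs.

## Task modes

* `screen_library()` encodes the pocket once and scores each molecule by
  projected-CLS similarity — no joint pass, so cost is linear in library
  size.
* `fish_targets()` runs one joint pocket-grounded pass per candidate
  pocket and scores by the matched-class probability.
* `dock()` iterates joint encode → coordinate head for `recycles + 1`
  rounds (default 0 during pre-training, 2 for docking inference) and
  reads the docking score from a final pass.
* `rank_poses()` scores candidate poses without moving atoms (rescoring
  semantics) and ranks them.

Metrics: AUROC (rank-sum, ties one half), BEDROC (Truchon–Bayly, default
α = 80.5, the community convention), enrichment factors in the hit-rate
ratio convention `EF_f = (hits/⌈fN⌉)/(n_actives/N)`, plain atom-order RMSD
with no superposition (the pocket frame is fixed), and the top-k / 2 A
success-rate protocol for docking power.  Symmetry-corrected RMSD is not
implemented; the synthetic ligands are asymmetric chains, so plain RMSD is
exact for them.

## The synthetic lock-and-key generator

`generate_complex()` builds matched complexes with a *planted, verifiable
signal*:

* the pocket is a partial spherical shell (48 atoms at 7 A by default, a
  polar cap left open as a mouth) of typed atoms;
* the ligand grows as a self-avoiding chain (12 atoms, 1.5 A steps,
  nonadjacent separation ≥ 1.2 A) inside the 4 A cavity;
* each ligand atom's element is a fixed permutation (the complementarity
  map) of its nearest pocket atom's element;
* Gaussian jitter (σ = 0.1 A) is applied last.

Chain geometry at 1.5 A steps matches covalent bond lengths; shell and
cavity radii keep the closest pocket–ligand approach above 1 A (no
clashes) while keeping joint graphs at ~60 atoms, where the quadratic
pair cost is desk-fast.  Ligands are *not* chemically valid molecules —
the model consumes types and coordinates only, so valence correctness
would add cost without exercising any additional code path.

Negatives transplant a foreign ligand into a pocket (recentred at the
native ligand's position, so geometry is plausible but typing is wrong);
decoy poses apply a rigid transform scaled by bisection to hit a requested
RMSD within 10%.  A nearest-neighbour complementarity oracle
(`complementarity_fraction()`) verifies the planted signal: matched pairs
score near 1, transplanted ligands near chance, and the oracle separates
actives from decoys with AUROC > 0.8 on generated libraries.  This bounds
from above what a trained model can exploit and makes the toy-training
checks meaningful: what those checks show is that the architecture and
losses can discover a planted geometric/typing signal at desk scale — not
that the model performs at any particular level on real proteins, whose
chemistry (solvation, flexibility, tautomers) the generator does not
emulate.

Everything the generator emits is a pure function of (spec, seed, call
index); datasets regenerate bit-identically and manifests record spec,
seed, counts and file digests.

## Numerical choices and limitations

* Float64 throughout (R's native numeric); softmax uses max-subtraction;
  summation order is fixed, so single-threaded runs are bit-reproducible
  and checkpoints round-trip exactly.
* Forward and backward passes are hand-derived matrix algebra, verified
  against central finite differences on small configurations in the test
  suite.
* Ties in ranked tables break deterministically by item id.
* The desk-scale reference configuration is L = 2 blocks, H = 4 heads,
  d = 64, G = 16 kernels, k = 128 projection, batch 8; toy runs use 300
  training steps (500 for retrieval), 8–64 synthetic complexes, and
  finish in minutes on one CPU.  The production regime such architectures
  are typically trained in (hundreds of thousands of complexes, GPU
  clusters) is out of scope here; no claim about benchmark-level screening
  or docking accuracy follows from the desk-scale checks.
* Pocket atoms are never moved by the coordinate head; pocket flexibility
  is not modelled.
* `read_pocket()` handles ATOM records only (no mmCIF, no heteroatom
  cofactors); alternate locations resolve to the highest-occupancy
  conformer.
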