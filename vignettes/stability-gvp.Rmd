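---
title: "Predicting protein thermostability changes with geometric vector perceptron graph networks"
author: "stabgvp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein thermostability changes with geometric vector perceptron graph networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabgvp)
```

## The problem and the model

A point mutation changes a protein's folding free energy by ΔΔG
(kcal/mol); its sign decides whether the mutant is more stable
(stabilizing) or less stable (destabilizing) than the wild type. This
package treats the prediction as binary classification rather than ΔΔG
regression: squared-error regression ignores the sign of its residual,
which is exactly the quantity of interest when triaging mutants, and
classification is the more learnable target when curated data are
scarce.

The classifier consumes *two* structures — wild type and mutant — as
residue graphs and learns the difference between them. Each graph
carries four feature families:

- **Sν (node scalars):** concatenation of up to six per-residue encoder
  families (one-hot 20, Atchley factors 5, PSSM 20, structure potential
  1, per-residue scoring terms 20, dihedral sin/cos 6; total width 72).
- **Vν (node vectors):** three unit vectors per residue — toward the
  next CA, toward the previous CA, and an imputed side-chain direction
  from idealized tetrahedral backbone geometry.
- **Se (edge scalars):** the CA–CA distance of each directed
  k-nearest-neighbour edge expanded over Gaussian radial basis
  functions.
- **Ve (edge vectors):** the unit displacement between the two CA
  atoms.

A geometric vector perceptron (GVP) maps a (scalar, vector) tuple to a
(scalar, vector) tuple: vectors pass through learned linear mixings and
are gated by sigmoid activations of the scalar path; scalars mix the
input scalars with the *norms* of the transformed vectors. Because every
vector operation is a linear mixing or a scalar gating, vector outputs
rotate exactly with the input and scalar outputs are unchanged —
the property the whole architecture inherits.

The network stacks 3 GVP-GNN message-passing layers. A message for edge
j→i chains 2 GVPs over the concatenated (source node, edge, destination
node) tuples; incoming messages are mean-aggregated, residual-added with
dropout on the scalar channel, and tuple-normalized (layer norm on
scalars, row-wise RMS normalization on vectors). A feedforward chain of
4 GVPs with residual follows. Both graphs share encoder weights
(siamese), so wild-type and mutant embeddings live in the same space.
Jumping-knowledge aggregation concatenates all three layer outputs
before mean-pooling per graph; the two pooled embeddings interact
through multi-head attention (with two tokens, the per-query softmax
reduces exactly to a sigmoid of the score difference); an affine +
sigmoid head emits P(stabilizing), thresholded at 0.5.

## Sign conventions

The literature uses both "positive ΔΔG = stabilizing" and the
folding-energy reading in which a stabilized fold sits at *lower* energy
(stabilizing = negative). Silent inference would corrupt labels, so the
convention is an explicit argument everywhere
(`classify_label(..., convention =)`), defaulting to
`"stabilizing_positive"`. An exact zero is labeled destabilizing with a
warning; records with only a ΔTm are labeled from its sign under the
same convention (no ΔΔG/ΔTm conversion is attempted — none is published
for mixed-condition data).

## Thermodynamic augmentation

**TL (looping).** If variants A and B share a wild type W, energy
conservation around the cycle W→A→B→W fixes
ΔΔG(A→B) = ΔΔG(W→B) − ΔΔG(W→A). `tl_augment()` emits all ordered pairs
of distinct variants with numeric ΔΔG, referencing A's mutant sequence
and its sequence diff to B. Pairs whose derived |ΔΔG| falls below 1e-9
kcal/mol are skipped: their sign, which is the label, is undefined.
Derived records with a single-mutation diff are routed to a separate
set, since they enlarge the single-point training pool. One pass is
performed; iterating TL to closure would only generate linear
combinations of existing measurements while compounding their
experimental error.

**TR (reversibility).** ΔΔG(Y→X) = −ΔΔG(X→Y), so every record yields a
reverse record with swapped reference, inverted mutations, negated ΔΔG
and flipped label. This exactly doubles a deduplicated dataset and
balances the stabilizing/destabilizing classes — experimental databases
are destabilizing-heavy, which otherwise biases training.

## The clustering splitter

Multiple-point records are characterized by their *combination of
mutation types* (the (from, to) residue pairs, positions deliberately
ignored). Records are multi-hot encoded over the observed type
vocabulary, unique combinations are embedded to 2-D with t-SNE
(perplexity 30, clamped to (n−1)/3 on small sets; 300 iterations with
early exaggeration; fixed seed) and clustered with DBSCAN (min_samples
5; eps from the largest gap of the k-distance curve unless given).
t-SNE runs on unique combinations with record back-mapping, so duplicate
records cannot reweight the embedding; this is an assumption the
splitter records in its manifest. Noise points (label 0) go to train.

Allocation fills each cluster's quota (round-half-up of cluster size ×
test fraction) by drawing wild-type proteins in seeded random order and
moving them *whole* — all their records across all clusters — into the
test set, so no wild-type sequence can leak across the partition. When
every remaining candidate would overshoot the quota, the smallest-data
candidate is taken only if the overshoot stays within one typical wild
type's worth of records (the dataset-wide mean per protein); otherwise
the cluster under-fills and the shortfall is reported in the manifest,
not hidden. Real data show both situations: clusters dominated by a
single heavily-measured protein cannot reach their quota without
flooding the test set.

## Numerical choices

- **k-NN ties:** distances are quantized to 1e-6 Å before ordering and
  ties break by residue index. This makes graph construction exactly
  deterministic and invariant under rigid motions, whose floating-point
  noise would otherwise reorder equidistant neighbours (ideal helices
  have many exact ties).
- **RBF edges:** 16 centers evenly spaced over [0, 20] Å, width equal
  to the spacing, so a distance at a center activates that basis to 1
  and the argmax center recovers the distance within one bin.
  Connectivity defaults to k = 30 neighbours, following the GVP-GNN
  lineage; both are configuration.
- **Termini and breaks:** undefined dihedrals (first φ, last ψ, angles
  spanning a chain break, detected by CA–CA distance outside
  [2.5, 4.5] Å) are encoded (0, 0) with a validity mask; missing
  forward/backward orientation vectors are zero vectors, which the
  GVP's gating maps to zero outputs rather than garbage.
- **PSSM squashing:** raw log-odds pass through a logistic transform
  (scale 2) to (0, 1); the transform is monotone, so profile ordering
  is preserved, and configurable (`transform = "none"` keeps raw
  scores).
- **Structure potential:** the structure-based family ships as a
  contact-count stand-in (CA neighbours within 10 Å, normalized by the
  structure's maximum) behind a pluggable registry
  (`register_structure_encoder()`), so a quasi-harmonic residue
  potential can replace it without touching the graph builder.
- **Optimization:** Adam with L2 weight decay on binary cross-entropy
  computed on logits in the numerically stable softplus form; dropout
  applies to scalar channels only (vector channels are normalized, not
  dropped). All randomness — initialization, batching, dropout, fold
  assignment — derives from the configuration seed.
- **Bias-mark thresholds:** the absolute accuracy difference is rounded
  to 9 decimals before threshold comparison so that, e.g., 0.9 − 0.7
  lands on the ≤ 0.2 side despite floating-point representation.

## Training protocol

Pretraining on single-point data uses 5-fold seeded cross-validation
with the published hyperparameters (3 layers, 2 message GVPs, 4
feedforward GVPs, hidden 182, batch 64, dropout 0.6, lr 1e-4, Adam
weight decay 1e-3), reporting per-fold and mean±sd accuracy, precision,
recall and AUC; single-class validation folds are skipped with a report
entry. Validation-based early stopping (patience 10) rotates within
folds — the standard reading of an 80/20 train/validation split.
Fine-tuning on multiple-point data updates *only* the GVP-GNN layer
parameters (lr 1e-3, weight decay 1e-6, dropout 0.4); embeddings,
attention and the head stay bit-identical, a scope switchable to full
fine-tuning. Multi-head attention defaults to 4 heads over a 128-wide
token (the head count and width are not constrained by the published
description; 182 is not divisible by 4, so the attention width is a
separate, divisible parameter).

## Equivariance: what holds and what cannot

Scalar features and the predicted probability are invariant under
proper rigid motions (rotations + translations) of the input
structures, and vector features transform exactly with the rotation —
this is verified over random motions in the test suite. Under
*reflections*, strict featurization-level invariance is impossible for a
chiral molecule: backbone dihedral sines and the cross-product component
of the imputed side-chain direction flip sign (a mirrored protein is a
different stereoisomer). The *network* is nevertheless
reflection-invariant given its vector inputs — scalars depend only on
norms of linear vector mixes — and the suite verifies probability
invariance under improper orthogonal transforms applied to the graph's
vector channels directly.

## The synthetic generator

`gen_helix_backbone()` builds ideal α-helices (φ = −57°, ψ = −47°,
ω = 180°, standard bond geometry) by internal-coordinate extension, with
optional jitter ≤ 0.1 Å. `gen_mutation_dataset()` emulates the
statistical shape of curated thermostability data: shared wild types
(so TL pairs exist), a two-Gaussian ΔΔG mixture with controllable
stabilizing fraction (default 0.3, mirroring the destabilizing majority
of experimental databases; magnitude 1.5 ± 0.8 kcal/mol, a typical
single-mutation scale). `gen_classification_fixture()` makes the label
recoverable from the mutant's residue composition, giving a solvable
sanity task.

What passing on these fixtures shows: the machinery is correct —
augmentation conserves counts and cycles, features respect geometry,
gradients are exact, the model can fit a signal that is present. What it
does not show: predictive accuracy on real mutations. The fixtures have
idealized geometry, uniform random sequences and no real energetics;
published-scale accuracy claims require curated experimental databases,
relaxed mutant structures and GPU-scale training, all outside this
package's scope.

## Problem sizes used in the checks

The automated checks run at desk scale: 8–50-residue backbones, graph
pairs of 12 residues with k = 8, hidden widths 8–16 for property tests,
a 32-sample separable set for the overfitting sanity check, and
synthetic datasets of 1,424–5,936 records for count-conservation
checks. These sizes were chosen so the full suite exercises every code
path in about a minute while leaving the architecture identical to the
full-scale configuration.

## Known limitations

- The ΔΔG values of public databases mix measurement conditions (pH,
  temperature); the package models the labels, not the noise process.
- Mutant structures are consumed, not modeled: generating them (e.g. by
  constrained all-atom relaxation) is an external step, and prediction
  quality inherits their quality.
- PSSMs and per-residue scoring tables are likewise external inputs;
  only their schemas and synthetic stand-ins live here.
- Single-chain backbones only; no side-chain atoms beyond the imputed
  direction; no multi-chain complexes.
- ΔΔG regression is deliberately out of scope; the classifier's
  probability is a confidence, not a calibrated free energy.
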