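---
title: "Methods: contrastive drug-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrastive drug-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`ddapred` predicts drug–disease associations from two modalities: a drug's
SMILES string and a disease's textual description. The pipeline has four
stages — encoding, attention pooling and field fusion, contrastive
enhancement, and Random-Forest scoring — followed by a complete evaluation
protocol. This vignette records the model, its assumptions, the parameters
that matter, and the design choices made where the design was genuinely
open.

## Encoding and pooling

**Drugs.** An encoder adapter turns a SMILES string into a token-level
embedding matrix with at most 512 rows (longer token sequences are
truncated). A two-layer feedforward scorer with tanh activation assigns each
token a scalar score; a softmax over scores yields pooling weights, and the
drug vector is the weighted sum of token embeddings. The softmax subtracts
the row maximum before exponentiation, so scores of any magnitude are safe,
and the pooled vector always lies in the convex hull of the token rows.

**Diseases.** Each of the three text fields (name, synonyms, definition) is
encoded to a fixed-width vector; the aggregate first-position representation
stands for the whole field. Fields are fused by a normalized weighted mean
with configurable nonnegative weights (default 1, 1, 1 — we found no
principled reason to prefer one field a priori, and the weights are exposed
for tuning). Fields that are empty are dropped and the weights renormalized
over the fields present; an all-empty record is rejected upstream because a
disease must have a name. The fused 768-vector is projected to 128
dimensions by a seeded random linear map.

**Adapters.** Pretrained transformer encoders are deliberately behind a
pluggable contract (`dda_adapter`): any object providing `encode_drug`,
`encode_text` and dimension metadata works. The package ships three offline
adapters: a hash-based mock (deterministic pseudo-random embeddings, no
semantic signal — the null tier), a one-hot entity-identity adapter (the
identity-memorization tier), and an oracle adapter that embeds the known
latents of a synthetic dataset (the informative tier). All package tests run
on these, so the full pipeline is exercised without downloads.

**Attention parameters.** The hidden width of the scoring MLP defaults to
h = 128. The scorer's parameters are drawn from seeded scaled Gaussians and
left at initialization: the pooled vector is a convex combination of token
embeddings either way, and for the oracle and hash adapters — whose token
embeddings share a common per-drug signal — training the scorer cannot
change what is recoverable downstream. Mean pooling (the `no_att` ablation)
replaces the softmax weights with uniform ones. Propagating the contrastive
gradient into the pooling scorer is a natural extension but is not
implemented; with pretrained encoders whose tokens differ in informativeness
it would likely matter more.

## Contrastive enhancement

Two projection heads (affine → ReLU → affine → layer normalization) map the
pooled drug vector and the projected disease vector into a shared space of
dimension `proj_dim`. Layer normalization uses the population variance with
eps = 1e-5 and no affine parameters, so an all-zero pre-normalization row
maps to zero — the documented degenerate-input convention.

Training minimizes an InfoNCE loss: for a batch of B known positive pairs,
the B×B similarity matrix of projected drugs against projected diseases is
divided by the temperature τ, and each positive's loss is the negative log
probability of its own disease under a softmax over the batch row. Design
choices:

* **Reduction.** The loss is the *mean* over positives rather than the sum,
  so its scale is batch-size independent; this changes only the effective
  learning-rate scale.
* **Negatives.** In-batch only; no hard-negative mining, momentum encoders
  or memory queues. Duplicate entities inside a batch can create false
  negatives; with thousands of entities and batch 256 this is rare and was
  accepted.
* **Direction.** The loss is drug→disease only (rows are drugs); a
  symmetric term was not added because the asymmetric form already aligns
  both heads through their shared gradient.
* **Projection dimension.** The architectural description suggests 128 while
  the tuned configuration reports 256; `proj_dim` defaults to the tuned 256
  and is a config knob.
* **Optimization.** Adam (β₁ 0.9, β₂ 0.999) at learning rate 5e-4, gradients
  derived analytically (including the layer-norm backward pass). 10% of
  positives are held out; training stops when the held-out loss has not
  improved for `early_stopping_patience` (default 5) epochs, and the best
  parameters are restored.
* **Interaction head.** A single affine layer + ReLU on the concatenated
  projections — the smallest head satisfying the contract that the output
  depend only on the concatenation. It is not part of the contrastive
  objective and stays at its seeded initialization.

The enhanced feature concatenates, in fixed order: pooled drug vector,
projected disease vector, both contrastive projections, and the interaction
vector. The `no_cl` ablation keeps only the first two blocks.

## Classification and thresholding

A Random Forest scores pairs; the score is the mean of per-tree class votes,
which is what ranking metrics require (a hard majority vote would discard
the ordering). Defaults follow the tuned configuration: 250 trees, depth cap
25, minimum 5 samples to split and 2 per leaf, square-root feature
subsampling, balanced class weights. The forest is fit by `ranger` with one
thread and a fixed seed; `min.node.size` carries the minimum-split rule and
`min.bucket` the minimum-leaf rule.

The binarization threshold maximizes the Youden index J(θ) = TPR − FPR over
all midpoints between adjacent distinct sorted scores plus ±Inf sentinels —
a finite, complete search space. Ties are broken toward the smallest
threshold, favoring sensitivity. The threshold is always selected on
training-fold scores and applied to the test fold, so test labels are never
read before threshold selection.

## Evaluation protocol

* **Balanced sampling.** Negatives are unknown pairs sampled uniformly
  without replacement, equal in number to the positives, drawn once before
  splitting so all folds share one universe.
* **Cross-validation.** Stratified 5-fold: within each label stratum pairs
  are shuffled and dealt so fold sizes differ by at most one and label
  balance is preserved per fold.
* **Cold start.** C1 holds out 20% of drugs (all their pairs become test);
  C2 mirrors for diseases; C3 holds out both and keeps as test only pairs
  with *both* entities held out, discarding pairs touching exactly one —
  the strictest leak-free reading. Degenerate C3 draws (empty test, or a
  single-class side) are retried with a derived seed a bounded number of
  times.
* **Metrics.** AUROC uses the midrank formula (ties count one half); AUPR
  uses step-wise average-precision interpolation with tied scores processed
  as one group. Ranking metrics treat drugs as queries ranking their
  test-fold candidate diseases (the per-disease direction is a flag);
  NDCG@10 uses binary gains and 1/log2(rank+1) discounts with ideal
  normalization, since no graded relevance exists. Queries without a
  relevant candidate are excluded with a warning.
* **Noise robustness.** Gaussian noise with SD equal to ρ times each
  feature column's clean-training SD can be injected into entity embeddings,
  enhanced features, or both, in the training phase, the test phase, or
  both (default both/both, matching the robustness protocol). Zero-variance
  columns are left untouched.
* **Feature quality.** Cosine similarities of up to 1,000 sampled positive
  and 1,000 negative pairs, summarized by class means, pooled-SD Cohen's d,
  and the AUROC of similarity as a classifier. A zero vector in a pair
  defines similarity 0.
* **Clustering.** Seeded KMeans (k = 6 by default, matching the six
  primary disease classes used for taxonomy diagnostics) on disease
  embeddings, scored by NMI and ARI against category labels plus the mean
  silhouette width.

## The synthetic benchmark

The generator emulates the *structure* of a curated association benchmark:
a sparse bipartite association table (the curated reference corpus has
density 0.0016 over 2,622 drugs × 1,455 diseases; the reference synthetic
configuration uses 200 × 150 at density 0.05 so desk-scale runs retain
enough positives per fold), SMILES-like strings from a tiny guaranteed-valid
grammar (chains over {C, N, O, S, F}, short branches, at most one aromatic
ring), and templated multi-field disease texts with category labels.

Associations follow a low-rank logistic model: drug latents are standard
normal in dimension 8; disease latents sit around one of six category
centroids placed on scaled coordinate axes with pairwise separation at least
max(3·noise_sd, 3) and within-category spread 0.5 — separated enough that
category structure is recoverable by clustering yet overlapping enough that
association prediction is not trivial. Each pair is positive independently
with probability plogis(u·v + b), with b solved by bisection (80 iterations
on [−60, 60]) so the expected density hits the target. Setting
`latent_scale = 0` suppresses the signal entirely, giving a pure-density
Bernoulli null.

What the generator does **not** emulate: real chemistry (the grammar is
syntactic only), realistic medical prose, the extreme sparsity and
popularity skew of curated corpora, and encoder biases of real pretrained
models. Passing tests on this benchmark therefore demonstrate that the
pipeline recovers a planted cross-modal signal and that every protocol
component is internally correct — not that any particular performance level
transfers to curated data with pretrained encoders.

## Problem sizes and seeds

The reference configuration (200 drugs × 150 diseases, latent rank 8,
density 0.05, encoder noise 0.3, full 384/768 embedding widths, proj_dim
256, 250 trees) is used for the planted-signal, shuffled-label and
contrastive-benefit checks and by `scripts/acceptance.R`. Repeated
experiments — cold-start ordering over 5 seeds and the 6-level noise sweep —
use a mid-size configuration (120 × 90, embedding widths 96/192, proj_dim
64, 120 trees, 25 epochs) chosen so each pipeline run completes in seconds
while leaving the planted signal comfortably recoverable. Every stage draws
its seed deterministically from one global seed via a mixing function, so
whole runs, including split files and reports, are bit-for-bit reproducible.

## Known limitations

* The attention scorer is not trained; its value is architectural
  (convex, interpretable token weights and the ablation surface), and
  exports of per-token weights are only as meaningful as the encoder behind
  them.
* In-batch negatives can include unobserved true positives (the standard
  contrastive-learning caveat), slightly biasing the loss.
* `min_samples_split` maps to ranger's `min.node.size`, whose splitting
  semantics match, but other forest internals (split criterion details,
  bootstrap RNG) are those of `ranger`, not of any other implementation.
* The similarity-network TopK neighbor parameters that appear in the tuned
  configuration have no described algorithm and are not implemented.
* Pretrained encoder adapters are intentionally out of the test surface;
  plugging them in changes embedding scale and geometry, and the enhancer
  learning rate or temperature may need re-tuning.
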