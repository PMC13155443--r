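---
title: "Detecting mislabeled image data with cross-validated ensemble voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mislabeled image data with cross-validated ensemble voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Supervised classifiers inherit every error in their training labels.  In
most benchmarks a few percent of labels are simply wrong, and in small
laboratory datasets — such as nanopore current recordings of adeno-associated
virus (AAV) capsids, where the classes *empty*, *ssDNA-filled* and
*dsDNA-filled* differ only through subtle current signatures — a handful of
mislabels can dominate what a model learns.  labelsieve implements an
offline quality-control stage that finds suspect labels before any
production model is trained, and proposes the likely true label for each.

## The detection procedure

Let $Q$ be a dataset of $N$ images with assigned labels over $K$ classes.

1. **Fold planning.** $Q$ is partitioned into $n$ near-equal subsets
   (default $n = 10$; a seeded shuffle precedes the split because segment
   images cut from one recording are temporally correlated).
2. **Cross-validation rounds.** In round $i$, each of $m$ base learners is
   built *fresh from its initialization seed* — no state crosses rounds,
   mirroring the way fine-tuned models are reset to their pretrained
   weights — and trained on the other $n-1$ subsets.  Every sample is
   therefore scored exactly once as unseen data; the package asserts this
   partition property, and the disjointness of training and held-out
   indices, on every run.
3. **Confidence-gated voting.** For held-out sample $q$, classifier $j$
   emits a softmax probability vector
   $P(y) = e^{z_y} / \sum_{k=1}^{K} e^{z_k}$ and the argmax decision
   $\hat y = \arg\max_y P(y)$.  The classifier casts an *eligible vote*
   against $q$ iff $\hat y \neq$ the assigned label **and**
   $\max_y P(y) > \delta$ (strict).  Low-confidence disagreements abstain,
   but abstentions never shrink the denominator: rules always compare vote
   counts against the full ensemble size $m$.
4. **Flag decisions.** With $v(q)$ eligible votes, majority filtering (MF)
   flags $q$ when $v(q) \ge \lfloor m/2 \rfloor + 1$ ("more than half"),
   consensus filtering (CF) when $v(q) = m$, and any custom $k/m$ rule when
   $v(q) \ge k$.  Flag sets are nested by construction:
   CF $\subseteq 4/5 \subseteq$ MF$(3/5)$ for $m = 5$, and every flag set
   shrinks monotonically as $k$ or $\delta$ grows.
5. **Label recovery.** A flagged sample receives the plurality of the $m$
   predicted labels; ties break by the largest probability mass summed over
   the tied classes, then by the lowest class index.  (The plurality and
   mass tie-breaks matter in practice only for weak ensembles; confident
   ensembles are unanimous.)

Training minimizes the categorical cross-entropy
$L(y, \hat y) = -\sum_{k=1}^{K} y_k \log \hat y_k$ over one-hot labels by
minibatch gradient descent.

Detection quality against a known injection is summarized by
$\mathrm{precision} = TP/(TP+FP)$, $\mathrm{recall} = TP/(TP+FN)$ and
$F_1 = 2PR/(P+R)$, where a flagged clean sample is an FP and an escaped
injected mislabel an FN.  Zero-denominator cases report 0 with an
`undefined` marker.  `detection_sweep()` re-tallies one frozen prediction
set over the full $\delta \times$ rule grid, so threshold comparisons are
not confounded by retraining noise — retraining per cell would change the
predictions that all cells are meant to share.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_subsets` | 10 | cross-validation rounds; each sample held out once |
| `m` (ensemble size) | 5 (or 3) | base learners voting per sample |
| `delta` | 0.5, grid 0.5–0.9 | strict softmax gate for a vote to count |
| `rules` | MF, CF (3/5, 4/5, 5/5, 2/3, 3/3) | votes required to flag |
| `epochs` | 30 (fine-tuning), 15 in the bundled experiments | passes per round |
| `learning_rate` | 0.001 (fine-tuning default) | fixed step size |
| `batch_size` | 32 | minibatch size |

The `train_config()` defaults (30 epochs, fixed learning rate 0.001, batch
32) are the fine-tuning regime, where only a small replacement head moves.
The bundled desk-scale experiments train tiny CNNs *from scratch*, where
that rate is far too small to leave the initialization; they use
`learning_rate = 0.05` with classical momentum 0.9 for 15 epochs, chosen
once when the experiments were designed.  Momentum is part of the
configuration surface and off by default.

## Base learners

The ensemble contract is minimal: build deterministically from a seed,
train on labeled images, emit normalized probability vectors.  Four
families implement it:

* **`tiny_cnn`** — a 3×3 convolution (8 filters, ReLU), 2×2 average
  pooling, one dense ReLU layer whose width is the variant, and a K-unit
  softmax.  Varying the dense width (16/32/64/128/256 in the five-member
  default) yields a near-homogeneous but diverse ensemble.  Everything is
  expressed as dense BLAS products via a precomputed im2col expansion that
  is shared across classifiers and rounds.  Inputs are shifted to
  $[-0.5, 0.5]$ before the convolution: zero-centered inputs keep the
  optimization stable whether the image background is dark (template
  shapes) or light (trace renders) — with raw $[0,1]$ intensities the
  nearly-constant white background of trace images drives the net into the
  uniform-prediction fixed point.
* **`finetune_backbone`** — the head-replacement recipe: a frozen feature
  extractor followed by three new fully connected layers of decreasing
  width (default 256 → 64 → K, ReLU between, softmax out).  The extractor
  is any `function(images) -> features`; the built-in `avgpool8` is a
  block-averaging stand-in so the recipe is exercised without downloading
  pretrained weights.  Published backbone widths are not specified beyond
  "decreasing", so the head widths are configurable.
* **`oracle`** — predicts the true label with probability 1.  It exists so
  that the vote logic can be verified *exactly*: with oracle members the
  detector must return precisely the injection record (no FP, no FN,
  recovery 1.0), independent of any training behavior.
* **`noisy_oracle`** — predicts the true label with probability
  $1-\varepsilon$, otherwise a random wrong class, with confidences drawn
  near 1.  It gives sweep tests realistic imperfect records at zero
  training cost.

## What the synthetic generators emulate — and what they do not

**Nanopore traces.** `simulate_trace()` emits a constant open-pore baseline
(default 10 current units) plus Gaussian noise (σ = 0.05), with
translocation events as rectangular blockades: Poisson event count
(default 8 events/s), normal depth and dwell (2 ± 0.5 ms) per class.  The
three default classes differ only in blockade depth — 0.5 (empty), 1.5
(ssDNA), 3.0 (dsDNA) — emulating how capsid cargo deepens the current
deflection.  The default sampling rate of 250,000 samples/s makes a
one-second segment exactly 250,000 points.  `segment_trace()` cuts
non-overlapping equal windows (trailing remainder dropped, since the
models need fixed-size inputs) and `render_segment()` rasterizes each
window as an axis-free line plot with a deterministic min–max-per-column
painter on a *fixed* vertical scale of (5.5, 10.5) shared by all segments
— per-segment autoscaling would leak class information through the axis
range.  Values outside the scale clip with a warning; overlapping
double-depth events do clip occasionally, which is accepted as the lesser
evil.  The renderer is a pure array function, so identical windows give
byte-identical images; graphics devices would not guarantee that.

Not emulated: electrokinetic physics, real AAV current amplitudes, drift,
1/f noise, event substructure, or the binary acquisition format.  Passing
tests therefore demonstrate that the *detection machinery* behaves as
specified on signals with the right coarse structure, not that any
particular accuracy carries over to laboratory recordings.

**Stand-in images.** `make_stand_in_dataset()` draws ten deterministic
template shapes (disk, ring, bars, cross, X, …) perturbed by integer
spatial jitter (σ = 1 px) and pixel noise (σ = 0.05) at 24×24 px.  It
plays the role of a generic well-separated 10-class image set: the jitter
and noise dials control separability continuously down to chance.

**Injection.** `inject_mislabels()` flips `count` distinct uniformly
chosen samples to a uniformly chosen *different* class, records every flip
(the target-class distribution is not specified beyond "random"; uniform
over the other K−1 classes is the least-assumption choice and is recorded
for exact scoring), and preserves the originals as `true_labels`.

## Numerical and design choices

* Vocabulary order is the lexicographic sort of class names, making
  one-hot positions reproducible across runs and platforms.
* Images are interchanged as 8-bit RGB PNG; in-memory intensities are
  quantized to the same 256-level grid, so save/load round-trips are
  bit-exact.
* Softmax subtracts the row maximum before exponentiation;
  cross-entropy clamps probabilities at $10^{-12}$.
* The $\delta$ comparison is strict (`>`): a confidence exactly at the
  threshold abstains.
* Argmax ties break toward the lowest class index.
* Fold sizes are $\lceil N/n \rceil$ or $\lfloor N/n \rfloor$, the larger
  folds first; no class stratification is applied (none is specified for
  the procedure), though the fold seed is exposed.
* `epochs = 0` is a valid configuration that evaluates the untrained
  initialization — useful for isolating vote logic.
* All randomness flows from explicit integer seeds through one
  deterministic derivation chain; the caller's RNG state is never
  disturbed.

## The bundled experiments and their scale

Two canonical experiments are exported so that code, tests and
documentation agree on one definition:

* `standin_flip_experiment()` — 10 classes × 100 images, 50 injected
  flips, five tiny CNNs over 10 folds, δ = 0.5, scoring MF(3/5) and
  CF(5/5) and reporting the smaller detected percentage.  The reference
  behavior for a well-separated set is full recovery under both rules.
* `balanced_nanopore_flip_experiment()` — the balanced three-class trace
  dataset (120 one-second segments per class, 360 images), 20 injected
  flips, three tiny CNNs, 2/3 voting at δ = 0.5; the reference behavior is
  that all 20 flips are identified.

These sizes (1000 and 360 images, 15 epochs, 32×32 and 24×24 px inputs)
were chosen as the smallest configurations that still exercise every stage
with confidently trained ensembles; both run in minutes on a single CPU
core.

## Known limitations

* The tiny CNN family is a desk-scale stand-in for large pretrained
  backbones; it demonstrates the ensemble mechanics, not state-of-the-art
  feature quality.  Real backbones enter through the
  `finetune_backbone` extractor hook.
* Recovery quality is only as good as ensemble plurality; with near-chance
  base learners the recovered labels are noise (the oracle tests bound the
  logic, not the learners).
* The simulator's rectangular-pulse model makes classes separable chiefly
  by blockade depth; detectors that succeed here may still fail on real
  recordings whose classes overlap in depth but differ in shape.
* Determinism is guaranteed on a single BLAS thread (the test and
  acceptance configuration); multi-threaded BLAS may reorder floating-point
  sums.
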