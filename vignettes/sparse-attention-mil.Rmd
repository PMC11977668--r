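---
title: "Sparse-attention multiple-instance learning for megapixel microscopy images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-attention multiple-instance learning for megapixel microscopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Histopathology images photographed through a microscope adapter are
megapixel-scale, but the clinically relevant evidence — clusters of abnormal,
hyperchromatic cells — may occupy a tiny fraction of the frame, and only an
image-level label ("normal" / "abnormal") is available. SparseMIL treats this
as multiple-instance learning (MIL): each image is a *bag* of all equal-sized,
non-overlapping square patches (*instances*), and a bag is abnormal if and
only if at least one instance is abnormal.

Every variant shares two building blocks:

* **Subnet 1**, a small convolutional encoder applied to every patch with
  shared weights: conv(16, 5×5, ReLU) → maxpool 3×3 → conv(32, 3×3, ReLU) →
  maxpool 2×2 → conv(64, 3×3, ReLU) → maxpool 2×2 → conv(128, 3×3, ReLU) →
  maxpool 2×2 → conv(128, 3×3, ReLU) → global average pooling, producing a
  128-vector per patch regardless of patch side (245,792 parameters).
* **Subnet 2**, a dense scoring head: dropout(0.5) → dense(256, ReLU) →
  dropout(0.5) → dense(1, sigmoid) (33,281 parameters).

The five variants differ in where aggregation happens and how:

| variant | aggregation target | pooling | parameters |
|---------|--------------------|---------|-----------:|
| EMIL_M  | embeddings | coordinate-wise max | 279,073 |
| EMIL_A  | embeddings | softmax attention   | 312,354 |
| IMIL_M  | instance scores | max            | 279,073 |
| IMIL_A  | instance scores | softmax attention | 312,354 |
| IMIL_SA | instance scores | sparsemax attention | 312,354 |

Attention variants add a module dense(256, tanh) → dense(1, sigmoid) on the
Subnet 1 embeddings, yielding one logit per instance; the logit vector `v` is
turned into a probability distribution by either

* softmax: `a_i = exp(v_i) / sum_j exp(v_j)` — strictly positive, so every
  instance retains weight; or
* sparsemax: the Euclidean projection of `v` onto the probability simplex,
  `a_i = max(v_i − Th(v), 0)` with the threshold chosen so the result sums
  to 1 — coordinates sufficiently below the leaders become *exact zeros* and
  those instances are discarded from the aggregate entirely.

Training minimizes the regularized objective

```
lossReg = lossNoReg + R_L0 + R_mer
```

where `lossNoReg` is class-weighted binary cross-entropy on the bag
probability, `R_L0 = lambdaL0 * #{a_i != 0}` counts the surviving attention
entries, and `R_mer = merSign * lambdaMer * sum_i a_i log a_i` is the entropy
penalty on the attention distribution.

## Design choices in the open corners

Several details are under-determined by the architecture description alone;
the package resolves them as follows.

**Final Subnet 2 width.** The scoring head is described with a 256-unit
sigmoid output, but the published whole-model totals (279,073 / 312,354)
reconcile only with a single sigmoid unit
(245,792 + 33,024 + 257 [+ 33,281]); the head therefore ends in one unit and
the totals are reproduced exactly, as `countParameters()` verifies.

**Sign of the entropy penalty.** The penalty is printed as
`lambda * sum(a log a)`. Added to a minimized loss with `lambda > 0`, that
term *raises* entropy, while its stated purpose is to *decrease* entropy and
make the attention vector more sparse. `merPenalty()` implements the formula
exactly as printed (`merSign = +1`, the package default) and exposes
`merSign = -1` for the entropy-minimizing variant that matches the stated
intent. The end-to-end examples and the acceptance run use `merSign = -1`:
with `+1` the attention distribution is actively pushed toward uniform and
sparse localization cannot emerge.

**Where L0 is measured.** Pre-transform logits are never exactly zero, so the
count is taken on the post-sparsemax attention probabilities, where exact
zeros occur. The indicator is piecewise constant: `R_L0` contributes its
value to the objective and to model selection but no gradient; a smooth
surrogate `lambda * sum(1 − exp(−a²/σ²))` (σ = 0.01) is available via
`smoothL0 = TRUE` for users who want gradient pressure from it.

**Attention logit range.** The attention module ends in a sigmoid, as
specified, confining logits to (0, 1). A consequence worth knowing: the
sparsemax support of a vector confined to a unit interval is never a single
instance (a gap of ≥ 1 to all others would be needed), so a trained IMIL_SA
typically retains a small subset — on the synthetic scenario roughly
10–40 of 81. `attentionSigmoid = FALSE` removes the sigmoid for ablation.

**Initialization.** Convolution weights are He-uniform; the dense heads are
Glorot-uniform. With Glorot convolutions the activations shrink roughly
thirty-fold across the five ReLU stages, all instance scores collapse to
≈ 0.5, and short training runs stall in that lazy regime; He init keeps
activation variance roughly constant and is the standard choice for ReLU
encoders. The attention module is initialized as a copy of the scoring
head (the two then train independently), so the initial attention ranks
instances the way the initial scores do. This matters for sparse attention:
with an independently initialized attention head, whether the initial
attention preference aligns or anti-aligns with true abnormality is a coin
flip per seed, and an anti-aligned start can evict the truly abnormal
instances — whose attention, and therefore gradient, is then exactly zero —
before the scorer has learned to rank them.

**Optimization.** Plain per-bag SGD with momentum 0.9 (configurable;
momentum 0 gives the textbook protocol). With one bag per step and attention
spreading gradient over dozens of instances, raw gradients are small;
momentum brings desk-scale convergence from hundreds to tens of epochs.
Learning rate defaults to 5e-3, the largest value of the canonical sweep
grid `(1e-3, 5e-3, 1e-4, 5e-4, 1e-5, 5e-5, 1e-6, 5e-6)`;
`sweepLearningRates()` reproduces the grid protocol and selects by
validation AUC. Model selection keeps the weights of the best
validation-AUC epoch, breaking ties toward the later epoch so that continued
training wins among equals. Class imbalance is handled by reverse class
weighting, `w_c = n / (2 n_c)`, as a per-bag loss multiplier.

Because the sparse-attention objective has distinct basins — the attention
either locks onto the discriminative instances or onto a self-consistent
but uninformative subset — the recommended recipe is restart selection,
`trainModelRestarts()`: several initializations are trained for a two-epoch
burn-in, the candidate with the best validation AUC (ties broken by lower
validation cross-entropy) continues for the remaining epochs. The wrong
basin is unmistakable at burn-in (validation AUC well below 1 and high
validation loss), which makes this cheap and reliable; the end-to-end
checks use five restarts.

**Numerical details.** The bag probability is clipped to
[1e-7, 1 − 1e-7] before the cross-entropy; `0 log 0 := 0` in the entropy
penalty; sparsemax uses a stable descending sort and its threshold formula is
tie-safe; max-pooling breaks ties toward the first index; dropout uses
inverted scaling at training time and is the identity at inference, so
`forwardBag()` is deterministic. The convolutional encoder runs in single
precision (im2col + SGEMM); permutation invariance of a bag forward pass
holds to well below 1e-6, and all double-precision invariants (loss
additivity, sparsemax-versus-oracle agreement) hold to 1e-9 or better.

## The pre-processing contract

`cropFieldOfView()` removes the dark surround outside the microscope's
circular field of view: pixels above 10% of the maximum intensity define the
tissue mask, and the square of side `min(H, W)` centered on the mask centroid
(clamped to the frame) is returned. A 4128 × 3096 frame with a centered
field of view crops to exactly 3096 × 3096. `tilePatches()` then cuts the
square into all non-overlapping patches of the requested side, row-major from
the top-left, discarding any remainder strip; the canonical patch sides
{344, 258, 172, 129, 86} divide 3096 exactly and give
{81, 144, 324, 576, 1296} instances. Tiling is lossless
(`untilePatches()` reassembles the original region bit-exactly).

## The synthetic scenario

No public dataset of smartphone-on-microscope cervical histopathology
exists, so `generateBag()`/`generateDataset()` emulate the acquisition: a
bright pink tissue texture (spatial frequency jittered per image by a
magnification factor in [0.8, 1.2], Gaussian pixel noise sd 8/255) inside a
circular field of view on a near-black surround; abnormal images receive 1–4
patch-aligned clusters of dark purple blobs standing in for hyperchromatic
nuclei, and the per-patch ground truth is recorded. Labels follow the MIL
axiom by construction. The default desk-scale configuration uses 774 px
images (one quarter of the 3096 px field) in 81 patches of 86 px — the same
bag size as the largest patch setting on full-size images — 120 images under
40 patients, abnormal fraction 0.747 (the 632/846 training balance of the
motivating cohort), split 60/10/30% patient-wise with greedy class-balance
stratification.

What the generator does *not* emulate: H&E stain variation, nuclear
morphology, focus blur, uneven illumination, or abnormality that is not
patch-aligned. Passing the end-to-end checks therefore demonstrates that the
implementation learns and localizes under the MIL assumptions — not that it
would reach any particular accuracy on real slides.

Generator defaults were chosen once for the scenario above; the abnormal
blob contrast makes planted patches linearly separable from normal ones by
mean color (≥ 95% at default noise), which is what makes the end-to-end
checks meaningful, and increasing `noiseSd` degrades that separability
monotonically.

## Problem sizes used by the checks

The test suite exercises forward/backward math at patch side 32 with small
bags, pipeline contracts at full 4128 × 3096 scale (cheap, deterministic),
and the learning checks on the default 120-bag scenario with 15 training
epochs; `scripts/acceptance.R` re-runs the same scenario end-to-end
(IMIL_SA, lambdaL0 = lambdaMer = 0.005, merSign = −1, lr 5e-3, momentum
0.9, five-restart burn-in selection) and reports held-out AUC/accuracy/F1
over the 48 validation + test bags and the attention mass on planted
abnormal patches over the 36 positive held-out bags. On one CPU the full
scenario (generation, training, evaluation) takes about ten minutes.

## Known limitations

* The exact L0 term is zero-gradient by nature; it shapes the objective's
  value and model selection, not the descent direction (the smooth surrogate
  is available, off by default).
* Sigmoid-confined attention logits bound how sparse sparsemax can get
  (support ≥ 2); this mirrors the published module design.
* The ResNet-50 baseline is a parameter-count reference
  (`buildResNet50Spec()`, 23,589,761 with conv biases and batch-norm moving
  statistics); no forward pass is provided for it.
* Patients in the synthetic generator group images administratively; no
  patient-level label correlation is modeled.
* JPEG input is not supported (PNG and TIFF are); images are assumed 8-bit
  RGB.
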