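---
title: "Scale-attention segmentation: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-attention segmentation: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanet)
```

## The problem and the model

Medical segmentation targets span enormous size ranges within a single
image: retinal vessel calibres run from a single pixel to several dozen,
lungs fill large smooth regions, and blastocyst tissue classes nest as thin
rings around large interiors. A plain U-Net extracts multi-scale context
only through its encoder pyramid; this package augments the U-Net *bridge*
(the deepest stage connecting encoder to decoder) with a **scale-attention
block** that builds a spectrum of receptive fields inside a single layer.

The block is a residual bottleneck. A 1x1 convolution maps the incoming
`in_channels` to `width` channels, which are split into `k` subsets
$x_1, \dots, x_k$ of `width / k` channels each. The subsets are chained:

$$
y_i =
\begin{cases}
x_i & i = 1\\
F_i(x_i) & i = 2\\
F_i\big(\mathrm{concat}(x_i,\, A_{i-1}(y_{i-1}))\big) & 2 < i \le k
\end{cases}
$$

where each $F_i$ is a same-padding 3x3 convolution with batch
normalization and ReLU, and $A_j$ is a **channel-attention gate**:
global max pooling and global average pooling reduce each channel to a
scalar, their sum passes through a 1x1 convolution and a sigmoid, and the
resulting per-channel gate in $(0,1)$ multiplies back onto its input.
Because $y_i$ is built from $y_{i-1}$, subset $i$ sees $i - 1$ additional
3x3 convolutions' worth of receptive field; the gate decides per channel
how much of the coarser context to forward. The first subset bypasses its
convolution, which keeps the parameter count nearly flat as `k` grows. The
$y_i$ are concatenated, fused by a 1x1 convolution back to `out_channels`,
and added to an identity skip.

Three ablation variants are provided for the bridge: `none` (plain
backbone), `resnet` (a conventional bottleneck: 1x1 reduce, one 3x3, 1x1
expand), and `res2net` (the same hierarchical split but with additive
coupling $y_i = F_i(x_i + y_{i-1})$ and no gates). Parameter counts
increase strictly in the order none < resnet < res2net < sa at any fixed
depth and width, which the tests verify against a closed-form layer tally.

## Design choices in the open corners

Several wiring details are genuinely open; the package fixes them as
follows and the tests pin the resulting behaviour.

* **$F_i$ composition.** 3x3 convolution + batch normalization + ReLU,
  matching the residual blocks the design descends from. Normalization can
  be disabled per block (`use_norm = FALSE`), which the zero-operator tests
  use.
* **Channel bookkeeping of the concatenation branch.** For $2 < i \le k$,
  $F_i$ maps $2\cdot$`width/k` inputs (subset plus gated previous output)
  to `width/k` outputs, so every stage's output keeps the subset width.
* **Attention gate shape.** The gate's 1x1 convolution maps C channels to
  C channels with a bias — no reduction ratio. The gate multiplies
  $y_{i-1}$ only; the concatenated map is not re-gated, and $y_k$ is not
  gated before fusion (the recurrence stops at $A_{k-1}$).
* **No activation after the skip addition.** The fusion 1x1 carries batch
  normalization but no ReLU, and nothing follows the residual add. This
  pre-activation-style choice makes a block with all-zero weights an exact
  identity — a property the tests assert bit-for-bit — and avoids
  rectifying away negative skip content.
* **Bridge placement.** The backbone keeps the conventional bottom double
  convolution; bridge blocks are *inserted after it* at the bridge width
  $C = \text{base\_width} \cdot 2^{\text{depth}}$. Insertion (rather than
  replacement of the bottom stage) is what makes every variant add
  parameters on top of the backbone, reproducing the published ordering of
  the ablation ladder.
* **Variant widths.** The ResNet bottleneck uses its canonical reduction,
  `width = C/4`; the split variants default to `width = C`. At these
  defaults the bottleneck is the cheapest bridge block and the gated split
  block the most expensive.
* **Initialization.** All weights draw from a fan-in-scaled uniform
  distribution through one explicit seeded stream; the same configuration
  and seed rebuild bit-identical parameter arrays.

The published parameter totals for the ablation ladder are not
reproducible — the exact backbone configuration behind them is not
recoverable — so only the ordering is asserted, never the absolute counts.

## Objective and training

Training minimizes mean per-pixel cross-entropy plus L2 weight decay:

$$
\mathrm{Loss} = -\frac{1}{n} \sum_{p=1}^{n} \log y'_{c(p)}
  \;+\; \beta \lVert W \rVert_2^2, \qquad \beta = 0.0002 ,
$$

the categorical form reducing to the familiar binary
$-\frac1n\sum y\log y' + (1-y)\log(1-y')$ at two classes because the
per-pixel probabilities are softmax-normalized. Probabilities are clamped
at $10^{-12}$ before the log. $\lVert W\rVert^2$ runs over every learned
scalar, biases and normalization parameters included — the simplest
consistent reading of "the weights". The optimizer is Adam (step size
1e-3, batch size 2 by default; the source never names an optimizer or
rate). Augmentation is rotation only: each batch is rotated jointly by one
angle drawn uniformly from [0, 360) degrees — images bilinearly, masks and
FOV by nearest neighbour, canvas preserved, corners filled with
background.

The final model is chosen by a plateau rule: the selected epoch is the
*last* epoch whose trailing window of 20 epochs fluctuates (max − min)
less than 0.01 in mean training loss; if no window qualifies, the final
epoch is used. The engine snapshots the weights whenever the trailing
window qualifies, so the returned model really is the selected epoch's.

All gradients flow through a small reverse-mode tape over NCHW arrays with
C++ kernels for convolution (im2col + BLAS), 2x2 max pooling and
transposed convolution. Analytic gradients are verified against central
differences to better than 1e-4 relative error through every layer type,
including batch normalization and the attention gates.

## Evaluation

Binary probability maps are thresholded at 0.5, strictly: a pixel at
exactly the threshold is background. Scoring is restricted to the field of
view when one exists. Confusion counts pool over all scored pixels of all
test images (micro-averaging), and cross-validation additionally reports
per-fold metrics and their mean — the published protocol does not say
which aggregation it used, so both are available. The suites are:

* vessel: SE, SP, ACC, MCC, F1, AUC (trapezoidal ROC area, computed as the
  tie-corrected rank statistic);
* lung: overlapping error $E = 1 - |P\cap T|/|P\cup T|$ (0 when both
  masks are empty), ACC, SE;
* artery/vein: scored on ground-truth vessel pixels only, arteries
  positive (a vessel pixel predicted background counts against the artery
  class), reporting SE\_AV, SP\_AV, BACC = (SE\_AV + SP\_AV)/2 and the two
  per-class F1 scores;
* blastocyst: per-class Jaccard indices and their unweighted mean.

Degenerate denominators return 0 by convention (SE, SP, F1, MCC). Every
metric is cross-checked in the tests against a brute-force oracle — pixel
enumeration, exhaustive positive-negative pair comparison for AUC, Pearson
correlation of indicator vectors for MCC — to 1e-9 on 200 random masks.

## Vessel diameter profiling

The calibre spectrum of a vessel mask is measured on its morphological
skeleton (Zhang-Suen thinning; the classic simultaneous-deletion rule can
erase an isolated 2x2 remnant, so a guard retains the deepest pixel when a
pass would delete everything). At each skeleton pixel the local diameter
is `2 * EDT - 1` pixel units, where EDT is the Euclidean distance to the
nearest background pixel: a straight strip of width w then measures
exactly w at its centreline, and diameters reach down to 1 for
single-pixel lines. Histogram modes over the skeleton recover the widths
of known test structures to within one pixel.

## Synthetic phantoms

The generators produce seeded, fully reproducible stand-ins with the
statistical structure of the four tasks — they are synthetic and make no
attempt at photorealism (no optic disc, no lesions, no CT texture):

* **vessel / av**: a disc field of view carrying branching trees of dark
  anti-aliased strokes on a bright background. Trees grow as queues of
  midpoint-displaced segments whose width decays by a factor of 0.7-0.9
  per generation from `max_width` down to ~1 pixel; the segment budget is
  sized so vasculature covers roughly 10-20% of the FOV, the density of
  real fundus images. The av variant interleaves two trees with different
  contrasts (labels artery = 1, vein = 2; veins overwrite at crossings).
* **lung**: two large smooth bright blobs (wobbly discs) on a dark
  background, covering 20-25% of the frame.
* **blastocyst**: five concentric noisy regions — background, zona
  pellucida ring, trophectoderm ring, blastocoel interior and an
  inner-cell-mass pocket — all present in every sample.

Background texture and additive noise both scale with `noise_sd`, so
`noise_sd = 0` produces a clean high-contrast image that a global
threshold segments at F1 > 0.95. That guarantees learnability headroom:
when the training tests demand F1 at or above 0.85 from a tiny network, failure
indicates a defect in the method, not an impossible task. Passing on
phantoms demonstrates that the architecture, gradients, training loop and
metrics are correct; it does not demonstrate clinical-grade accuracy on
real fundus, CT or embryo images, which vary in ways the phantoms do not
model.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes that still exercise every code path: 64x64
phantoms (128x128 defaults for the generators), a depth-2, width-8 network
with k = 4 for training runs (200 gradient steps), and depth-4, width-16
models for parameter accounting. The full-size configuration of the
original method (depth 4, base width 64, 512x512 inputs) is expressible
with the same `network_config`, only slower to train.

## Known limitations

* Batch normalization statistics are per-batch during training; with very
  small batches the running estimates used at evaluation can lag the
  batch statistics early in training.
* The thinning guard protects only a vanishing last remnant; interior 2x2
  blocks of larger shapes still thin in the classic (occasionally lossy)
  Zhang-Suen manner.
* `run_cv` retrains from the same initialization every fold by design
  ("same settings and training initialization"); it does not vary the
  seed across folds.
* The engine is CPU-only and single-threaded apart from BLAS; it is meant
  for desk-scale experiments, not full-dataset benchmark training.
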