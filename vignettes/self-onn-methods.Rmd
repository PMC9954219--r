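---
title: "Operational layers, the MBINet protocol, and the synthetic phantom generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational layers, the MBINet protocol, and the synthetic phantom generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbinet)
```

## The generative-neuron model

A convolutional neuron combines its inputs linearly before the
nonlinearity. The operational (Self-ONN) neuron implemented here replaces
each per-connection product with a learned polynomial nodal operator

$$\Psi(w, y) \;=\; \sum_{q=1}^{Q} w_q\, (y - a)^q,$$

a truncated Taylor expansion around $a$ whose coefficients are trained like
any other weight. The layer output for channel $k$ is
$b_k + \sum_i \Psi(w_{ki}, y_i)$, summed over input channels and the 3×3
window. Two consequences drive the implementation:

* **$Q = 1$ degeneracy.** With a single coefficient per connection the
  operator is a plain product, so the layer is numerically identical to a
  standard convolution. The test suite asserts this on 100 random
  parameterizations against an explicit-loop convolution oracle (max
  absolute difference < 1e−6), and the "vanilla CNN" zoo entries are the
  same graphs with $Q$ forced to 1.
* **Channel stacking.** $(x-a)^q$ can be precomputed per input channel, so a
  $Q$-order operational convolution is an ordinary convolution over $QC$
  power-stacked channels. The C++ kernel (RcppArmadillo) uses exactly this
  reduction: im2col over the power stack followed by a single GEMM, and the
  reverse chain $\partial (x-a)^q/\partial x = q(x-a)^{q-1}$ in the backward
  pass.

Activations are `tanh`; its $[-1, 1]$ range is what justifies fixing the
expansion point to $a = 0$ (the field stores $a$ anyway for generality). The
constant Taylor term $w_0$ is *not* stored per connection: a per-connection
constant is unidentifiable next to the per-channel bias, so it is absorbed
into $b_k$. Orientation is cross-correlation (no kernel flip) — the choice
is immaterial to a trained model but is documented so checkpoints are
unambiguous. Spatial padding is zero same-padding: the MBINet pooling
arithmetic (below) only reaches its stated flatten size if operational
layers preserve spatial extent.

Gradients are hand-written backpropagation rather than autodifferentiation;
the contract that matters — every weight and bias entry receives a gradient
consistent with central finite differences at relative error < 1e−3 — is
enforced by tests at layer level (exhaustively over a 4×4, $Q=3$ layer) and
through the whole stack including pooling and the dense head.

## MBINet and the variant zoo

The default MBINet is eight layers: seven operational layers with channel
schedule (8, 8, 8, 8, 8, 16, 32) and one dense softmax "MLP" head. 2×2
stride-2 max pools follow layers 1, 3, 5 and 7; a 3×3 stride-3 pool (floor
division, no ceil mode) precedes the flatten. On 224×224×3 input the
spatial trace is 224 → 112 → 56 → 28 → 14 → 4, giving 32·4·4 = 512 flatten
features and 28,006 trainable parameters — both verified against hand
counts in the tests.

The layer-count narration admits a second consistent reading with eight
operational layers, (8, 8, 8, 8, 8, 16, 16, 32), which is also
flatten-512-consistent; it ships as `mbinet_config(preset = "enum8")`
rather than being silently chosen. The shallower variants (4 and 6
operational layers, optionally one extra dense hidden layer, "1DN",
default width 64) have no published channel schedules; they reuse MBINet's
schedule truncated to depth with a widened final stage. These are plumbing
choices, configurable, and not claimed to reproduce any published variant
exactly.

Degenerate configurations (pooling below 1×1, or a flatten that misses a
declared length) are rejected at build time with an error naming the
offending stage.

## Preprocessing, augmentation, and the fold plan

Images are resized to the model input with bilinear interpolation and
z-score normalized per channel in storage order (R, G, B) with the fixed
statistics mean (0.2552, 0.4666, 0.8804), SD (0.4116, 0.3645, 0.2597); the
channel assignment of those triples is itself a convention, as the source
protocol does not state it. Whether they were computed on [0, 1] or [0,
255] pixels is equally unstated; since z-scoring is affine, the choice only
rescales the input and is absorbed by the first layer.

The augmentation menu is exactly ten deterministic transforms — rotations
±30° and ±10° (positive = clockwise in screen coordinates), magnifications
1.10 and 1.12 (center-cropped), translations (10%, 10%), (8%, 12%),
(−10%, −10%), and a vertical flip — so a training set expands tenfold
(1,320 → 13,200). Only five of the ten are enumerated in the source
protocol; the remainder are drawn once from its stated parameter ranges and
fixed. Exposed borders are filled with background 0.

The fold planner stratifies per class: seeded shuffle, contiguous fifths as
the test split of each fold, then `ceiling(0.2 · rest)` validation samples.
The ceiling rule is adopted because it reproduces every published per-class
validation cell (48, 35, 35, 32, 32, 31; total 213) on the reference class
counts (300, 215, 215, 200, 200, 190) — a stated alternative total of 231
is inconsistent with that per-class arithmetic and is not used. One
deliberate deviation: the published augmented counts equal 10× the *total*
class sizes, implying augmentation before splitting; this package augments
the **training split only**, because augmenting before splitting leaks
near-duplicates of test images into training. The tenfold arithmetic is
still exercised (and asserted) on the training side.

## Training schedule

Adam (β₁ = 0.9, β₂ = 0.999), categorical cross-entropy on the softmax
outputs — the loss is never stated in the source protocol; cross-entropy is
the standard choice for a softmax head. Defaults: lr 5e-4, batch 16, ≤30
epochs. "Validation loss remained constant" is operationalized as no
improvement > 1e−4 for 5 consecutive epochs; the same window drives a
reduce-on-plateau multiplier of 0.2, and the ambiguous "maximum epochs stop
10" is read as a hard floor of 10 epochs before early stopping may fire.
The returned fit carries the best-validation-loss parameters. Non-finite
loss raises a divergence error naming the epoch.

## Evaluation

The confusion matrix is 6×6 in fixed label order (NT, BT, MT, BBT, MMT,
BMT). Per-class metrics use one-vs-rest counts (accuracy, recall,
specificity, precision, F1); "weighted" is the support-weighted mean,
overall accuracy is trace/total, and zero-support classes are excluded from
weighting with a warning. All five formulas are checked to 1e−12 against a
brute-force per-sample tally on hundreds of random matrices. Percentages
are rounded half-up to two decimals where printed. The misclassification
audit inverts printed per-class recalls into integer error counts
(`support − round(recall·support)`).

ROC curves are one-vs-rest threshold sweeps; the single reported AUC is the
**micro-average** over the flattened class-membership problem (the
averaging scheme behind published single-number AUCs is unstated; macro is
available by flag). The sweep is cross-checked against both an independent
trapezoid oracle and pROC with a pinned curve direction.

## The synthetic phantom generator

The generator emulates the *statistical layout* of reconstructed microwave
head images, not their physics: a roughly circular head disk (radius
0.38–0.45 of the width, mild ellipticity and off-center jitter) with
low-frequency texture and Gaussian noise (SD 0.02), plus 0–2 high-intensity
blobs whose count and shape encode the class. Benign blobs are
near-circular ellipses (axis ratio 0.9–1.0) with a mild boundary wobble;
malignant blobs are radially perturbed stars (5–8 lobes). Shape classes are
*enforced by measurement*: a blob is re-drawn until its rendered mask's
circularity 4πA/P² — with a chain-code perimeter using
Vossepoel–Smeulders step weights, chosen because naive boundary counting
is badly biased for small digital disks — satisfies benign ≥ 0.85 or
malignant ≤ 0.70. The wobble amplitude scales with the benign cutoff, so
narrowing the circularity gap generates genuinely harder shapes; a test
verifies that this knob measurably confuses the rule-based oracle.

Intensity is rendered through a heat-map palette (dark blue background,
bright red/yellow foci) whose red channel is monotone in intensity, which
is what the rule-based oracle thresholds before connected-component
labeling. Tumor radii are floored at ~5 px so blobs stay resolvable;
below 64 px the two-blob geometry becomes infeasible and `phantom_params()`
refuses the size. Defaults make the oracle recover the true label on ≥99%
of images (measured 100% on 570 generated images during development) — the
point is that the classes are learnable *by construction*, so a failure of
the network to learn is attributable to the network, not the data.

What the generator does **not** emulate: reconstruction artifacts, antenna
geometry, inter-subject anatomy, intensity calibration of real microwave
images (no such statistics are published numerically), or class-conditional
correlations beyond blob count and shape. Passing the end-to-end test
therefore demonstrates that the implementation can fit a six-way,
shape-and-count discrimination task from a few hundred images — not that it
reproduces clinical performance.

## Problem sizes and numerical choices in the shipped tests

The test suite runs the full protocol at reduced scale, chosen to keep a
desk run comfortable: the end-to-end check trains MBINet at 64×64 input on
60/15/20 images per class for up to 30 epochs (≈2 minutes on one CPU) and
requires ≥90% held-out accuracy; the measured run reaches 97.5% with
micro-AUC 0.999 under its fixed seeds (seed sensitivity is real — a
different seed set measured 85% — which is why the bound sits at 90%).
Oracle and property tests use 3–7 px feature maps, 1–4 channels, Q ≤ 5.
Weight initialization (unstated in the source protocol) is symmetric
uniform with 1/√fan-in scaling applied per q-slice, so Q = 1 initialization
matches a standard convolution's; probabilities are clamped at 1e−12 inside
the loss; softmax subtracts the column maximum before exponentiation.

## Known limitations

* No GPU path and no minibatch-level parallelism; the implementation is
  desk-scale by design (the 64-px training run is ~2 min; a full 224-px,
  five-fold, augmented replication would be orders of magnitude slower).
* The operator-library ONN (sin/exp operator sets) is out of scope; only
  the polynomial nodal operator is implemented.
* Published headline numbers on the clinical dataset are not reproducible
  from synthetic data and are not claimed; the package reproduces the
  *protocol arithmetic* exactly and the *learning behavior* qualitatively.
* `simulate()`/`residuals()` methods are not provided: neither has a
  standard meaning for a softmax image classifier.
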