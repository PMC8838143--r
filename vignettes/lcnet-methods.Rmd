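---
title: "LCNet: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LCNet: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains what the package computes and why it is built the way
it is: the classification model, the data pipeline around it, the numerical
conventions, and the choices made where the design was genuinely open. It
states no empirical result beyond what the package's own tests compute.

## The problem

Dermoscopy produces magnified RGB images of skin lesions; the clinical task
is to separate melanoma (MEL) from benign lesions (BEN, which absorbs the
nevus and seborrheic keratosis subtypes). Public archives of such images are
imbalanced, contain near-duplicate submissions, and carry acquisition
artifacts — hair lines, gel bubbles, ruler marks. The package implements a
complete small-scale pipeline for this setting: dataset bookkeeping,
duplicate removal, geometric standardization, class balancing, a compact
convolutional classifier, and confusion-matrix/ROC evaluation.

## The model

`lcnetConfig()` describes an 11-block convolutional network with roughly
3.4 M learnable parameters and 3100 kernels across 31 convolutional layers —
small by modern standards, which is the point: the architecture targets
settings where a ResNet- or Inception-scale model is unwarranted.

Every convolution is followed by batch normalization and a LeakyReLU with
negative-branch slope 0.3 (so `leakyReLU(-1) == -0.3`). The layout is:

* **Stem.** 8 kernels of 3×3 at stride 2 on the 128×128×3 input, then 2×2
  max pooling: a 32×32×8 map.
* **Junction.** Block 1 (16@1×1 then 32@3×3) and block 2 (32@3×3) both read
  the stem output; their feature maps and the pooled stem map are
  concatenated channel-wise (32+32+8 = 72 channels).
* **Reduction blocks 3/6/9.** 1×1 convolutions with 36, 32 and 64 kernels,
  each followed by 2×2 average pooling, which carries the spatial trace
  32 → 16 → 8 → 4.
* **Repeat groups.** Three groups of two-branch units repeated 2, 4 and 2
  times. A unit applies two blocks in parallel to the same input and
  concatenates the results: a bottleneck branch (r@1×1 then m@3×3) and a
  direct branch (m@3×3), with (r, m) = (32, 64), (64, 128), (128, 256).
  Each unit therefore emits 2m channels (128, 256, 512 per group).
* **Head.** Global average pooling of the 512-channel map into a fully
  connected softmax layer over the classes.

Two wiring details deserve a note because alternatives exist. First, the
repeat units concatenate only their two branch outputs, not their input;
the input is re-concatenated only at the stem junction. This is the variant
whose structural totals come out at exactly 31 convolutional layers and
3100 kernels, the published shape of the design. Second, what is
concatenated from the stem's max pooling is the pooled feature map itself:
pooling *indices* are bookkeeping for unpooling, not a feature map, and
cannot be joined channel-wise. Block 3's 36 kernels break the otherwise
clean doubling pattern but are kept at face value. With these choices the
parameter total is 3,435,598 — about 4% above the published rounded 3.3 M
figure; no variant of the wiring consistent with the published description
closes that gap exactly, so the count is reported as computed rather than
adjusted. `networkStats()` computes all three totals structurally, without
instantiating weights, and the same graph-construction code builds the
runnable network, so the counted and the executed architecture cannot
drift apart.

The engine underneath (`src/ops.cpp`) implements im2col+GEMM convolution,
batch normalization, pooling and backpropagation in C++ with Armadillo.
Weights initialize with variance-scaling fan-in normal draws using the
LeakyReLU gain `sqrt(2 / (1 + 0.3^2))`; biases, BN offsets start at 0, BN
scales at 1. Initialization, shuffling and augmentation all draw from R's
RNG under the configured seed, so a run is reproducible end-to-end on one
machine. Conv biases are retained (and counted) even though the following
BN makes them redundant; their gradient is absorbed by the BN mean, which
is expected behavior, and keeping them matches the published parameter
accounting.

## Training

`TrainConfig` defaults to the canonical recipe: SGDM with learning rate
0.001, momentum 0.99, L2 regularization 0.0005, mini-batch 32, at most 100
epochs. The update is classical momentum,

v' = γ·v − α·(g + λ·θ), θ' = θ + v',

with the L2 term folded into the gradient (the common "coupled" weight
decay). The loss is weighted cross-entropy with inverse-frequency class
weights w_k = N/(K·n_k), computed over the original (pre-oversampling)
training counts; the weights average 1 when classes are balanced. Predicted
probabilities are clamped to [1e-12, 1] before the logarithm.

Early stopping monitors validation loss with a default patience of 10
epochs (the patience value is a package choice; the published account of
the procedure does not state one) and the weights of the best epoch are
restored. Batch normalization uses batch statistics during training and
exponentially tracked running moments (momentum 0.1, a standard default)
during evaluation; the running moments are not counted as learnable
parameters.

Class balancing is random oversampling: every class is brought up to the
majority count by drawing ids with replacement, with the drawn duplicates
flagged. Augmentation is online — each training image is re-transformed
every epoch with a random rotation in ±30°, a horizontal scale drawn from
[0.8, 1], vertical scale fixed at 1, and integer translations in ±5 px,
composed as a single affine map about the image center. Oversampled
duplicates therefore never enter training as literal copies. The rotation
bound is read as degrees: a ±300 range would be a full rotation and no
longer a bounded jitter. The scale setting is read as an anisotropic lower
bound (X drawn from [0.8, 1]) rather than a fixed squash, since a
deterministic transform applied to every sample would not be a random
augmentation. Exposed pixels after the affine map take the per-channel
median of the image, a skin-tone-like fill. Validation and test data are
never augmented.

## Preprocessing, deduplication and their conventions

Preprocessing is a center square crop (side `min(H, W)`, extra pixel
dropped from the trailing edge) followed by bilinear resize to 128×128.
The resampler uses half-pixel-centered mapping (`align_corners = false`):
output center i samples input coordinate `(i + 0.5)·S/target − 0.5` with
border replication. This is the dominant convention in modern imaging
stacks, and because frameworks genuinely differ here the package pins it
explicitly and implements the sampler itself (the same kernel drives the
augmentation affine), rather than inheriting a corner-anchored convention
from a third-party resizer. Bilinear weights are convex, so resizing can
never overshoot the input range, and resizing a 128×128 image to 128 is a
bit-for-bit identity — both properties are tested. No hair or bubble
removal is attempted; the classifier is expected to tolerate raw artifacts,
and the synthetic generator deliberately injects them.

Duplicate elimination converts images to grayscale (luma weights
0.299/0.587/0.114) and computes the Pearson-type normalized
cross-correlation of the two pixel grids about their scalar means. Images
of unequal size are both resized to 128×128 first so the grids align. A
pair correlating strictly above 0.99 is a duplicate; a greedy scan in
manifest order keeps the first occurrence. Two conventions are worth
stating: a constant image (zero variance) correlates at 0 by definition
here, with a warning, rather than NaN; and a histogram-based variant
(correlating the 256-bin intensity histograms instead of the grids) is
available via `mode = "histogram"` because the verbal description of the
procedure is ambiguous between the two readings — the pixel-grid form is
canonical since the correlation sum runs over spatial coordinates, which
only images have.

The stratified splitter assigns `round(f·n)` records per class to
validation and test (round half up) with the remainder to training, so the
canonical 0.70/0.10/0.20 fractions give exactly 70/10/20 per hundred. The
published per-class tables do not match exact fractions (their training
shares run below 70%), indicating additional undocumented curation; the
package implements the stated fractions and makes no attempt to reproduce
row-level membership.

## The synthetic generator, and what it does not show

`generateDataset()` renders lesion-like images so every stage is testable
without external archives: a beige-noise skin background; a centered,
jittered ellipse — dark, boundary-perturbed and heavily speckled for MEL,
lighter and smooth for BEN; optional hair arcs and bubble highlights;
optionally, exact duplicate copies (for deduplication tests) and per-class
imbalance multipliers. Defaults: 192×192 pre-crop size, artifact rates 0.3
(hair) and 0.2 (bubble), no duplicates, balanced classes. The class
profiles are intentionally easy — the class-conditional mean luma gap is at
least 20 intensity units by construction and is asserted on every generated
set — so that training-based checks are stable across seeds rather than
hostage to optimization luck.

This has a direct consequence for interpretation: passing the pipeline
smoke test (validation accuracy ≥ 0.90 after a few epochs on 200 images
per class) demonstrates that the network, loss, optimizer and data plumbing
are wired correctly, *not* that the model reaches any particular accuracy
on real dermoscopic archives. Real-data performance requires the actual
ISIC images and much longer training, both outside this package's test
scope.

## Numerical choices and degenerate inputs

* BN epsilon 1e-5; probability clamp 1e-12; early-stop improvement
  threshold 1e-12 (ties do not count as improvement).
* Zero-denominator confusion metrics return 0 with a `degenerate` flag
  rather than NaN.
* Argmax label ties break toward BEN.
* ROC/AUC: threshold sweep over unique scores, trapezoidal area; equals
  Mann–Whitney pair counting with ties at one half (tested against a
  brute-force pair count and against pROC).
* The oversampler requires at least one sample per class; the loss requires
  matching shapes; the splitter requires fractions summing to 1 within
  1e-9; constant-image correlation warns.

## Problem sizes used by the test suite

The suite exercises the full network at its native 128×128 input. The
pipeline check trains on 400 images (200 per class) with 80 held out for
validation for 5 epochs, and the learning-sanity check memorizes a
10-sample fixture for 5 epochs. The
oversampling-direction check compares minority recall with and without
balancing on a 4:1 imbalanced set for 3 epochs. These sizes are the
package's choice of a desk-scale experiment: small enough to run routinely,
large enough that a wiring or gradient error cannot pass.

## Known limitations

* Single-device, single-precision-free (double) CPU training only; no
  learning-rate schedules, no mixed precision.
* Lesion centering is geometric: the crop assumes the lesion is roughly
  central, as no localization algorithm is part of the design.
* The duplicate scan is O(kept × candidates) with full-resolution
  correlation; adequate for thousands of images, not millions.
* Binary task; the head widens to more classes (`lcnetConfig(nClasses)`)
  but the pipeline's label vocabulary is MEL/BEN.
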