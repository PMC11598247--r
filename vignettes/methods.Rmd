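---
title: "Nuclei segmentation and classification with attention-enhanced residual refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclei segmentation and classification with attention-enhanced residual refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aernet)
```

## The problem

H&E-stained histology patches contain many nuclei of several types
(epithelial, inflammatory, spindle-shaped, miscellaneous in colorectal
tissue), frequently packed into touching clusters, with strongly imbalanced
type frequencies. Two things make naive semantic segmentation insufficient:
touching nuclei must be separated into *instances*, and rare types must not
be swamped by the dominant class during training. This package implements a
network-plus-post-processing pipeline that addresses both, together with
everything needed to exercise it end to end on synthetic data: target
encoding, losses, watershed post-processing, evaluation metrics, a seeded
scene generator and a desk-scale training loop.

## Model

The network is an encoder–decoder with one shared encoder and three
structurally identical decoder branches:

* a **nuclear probability** branch (2 channels: background/foreground),
* a **horizontal–vertical (HV) distance regression** branch (2 channels),
* a **classification** branch (K + 1 channels including background).

The encoder is a ResNet-50-style stack of four bottleneck stages (unit
counts 3, 4, 6, 3 by default) modified in two ways: the stem convolution
has stride 1 and the initial max-pooling is removed, so stage 1 retains
full resolution and the total downsampling is 8x rather than 32x — nuclei
are small and detail matters; and each stage ends in a channel-attention
then spatial-attention block (CBAM-style: a shared bottleneck MLP over
global average- and max-pooled descriptors gates channels, then a 7x7
convolution over channel-pooled mean/max maps gates pixels). Each decoder
branch upsamples 2x three times (nearest neighbour), applies dense blocks
of 8 and then 4 dense units after the first two upsamplings, and merges
encoder features by elementwise addition through 1x1 projections.

Each branch ends in an **attention-enhanced residual refinement head**: a
compact encoder–decoder (3x3 conv + BN + ReLU + channel attention, then
2x2 max-pool, repeated `arrm_pool_stages` times; a bridge of the same
unit; mirrored upsample–convolution stages) that consumes the branch's
coarse prediction map and emits a residual correction:

```
refined = coarse + head(coarse)
```

Both coarse and refined predictions are supervised. The refinement head's
combination rule and its input are genuinely open design points — the
refinement literature it descends from supports several variants — and we
adopt the purely additive residual on the prediction map alone, which
keeps "disable the head" exactly equivalent to "refined = coarse" (a
property the tests assert). Whether the three heads share weights is
likewise open; they are independent here.

### HV target encoding

For every nucleus pixel the regression target is the signed offset to the
instance's center of mass, scaled per instance *and per side* so the
extreme left/top maps to -1 and the extreme right/bottom to +1; the
center of mass maps to exactly 0 even for asymmetric instances, and
background is exactly 0. A bounded, per-instance-normalized target is
needed for stable regression; the symmetric [-1, 1] range is the
convention of the distance-map family of models this design builds on.
Gradients of these maps peak *between* touching nuclei, which is what the
post-processing exploits.

### Losses

With `X` a prediction and `X-hat` its target, the composite objective is

```
L = alpha * L1 + L2,        Li = Li,a + Li,b + Li,c
```

where `L1` is computed from the coarse and `L2` from the refined maps
(`alpha` = 1 by default), and the branch terms are

* probability: `beta3 * CE + beta4 * Dice` (Dice smoothing
  `epsilon = 0.001`),
* distance: `beta1 * MSE + beta2 * gradient-MSE`, the latter comparing
  horizontal/vertical finite-difference gradients over the nuclear pixel
  set only (`beta2 = 2` is the recommended setting for crowded colorectal
  tissue),
* classification: `beta5 * CE + beta6 * generalized Dice`.

The generalized Dice loss weights each class by the inverse squared class
volume, `w_l = 1 / (sum_n r_ln)^2`, so rare nucleus types dominate the
loss long before they dominate the pixels; this is the package's lever
against class imbalance, and a dedicated test demonstrates that, for a
fixed prediction that is wrong on the minority class of a 90/10 fixture,
the generalized Dice loss strictly exceeds the unweighted multiclass Dice.

Numerical conventions worth stating: the cross-entropy log is floored at
1e-8 (the raw expression is undefined at zero probability); the
gradient-MSE of a nucleus-free patch is defined as 0 with a warning (its
normalizer is the nuclear pixel count); classes absent from the ground
truth are skipped in generalized Dice (their weight would be 1/0); and
the gradient operator inside the gradient-MSE is the same central
difference used to build the targets, so a perfect prediction scores
exactly 0. The cross-entropy normalizer counts pixels, not
pixels-times-channels.

### Post-processing

Instances are extracted from the predicted maps `q` (foreground
probability) and the HV pair by marker-controlled watershed:

1. Sobel responses of the two HV channels (aperture `sobel_ksize`,
   default 5) are each min–max rescaled and inverted so the steep negative
   transition between adjacent nuclei maps to 1, and combined by pixelwise
   maximum into a boundary energy `Sm` (constant channels contribute 0 —
   the degenerate rescale).
2. Markers `M = relu(tau(q, h) - tau(Sm, k))` are 8-connected components
   of confident-foreground-minus-boundary, cleaned of components smaller
   than `min_instance_px`; `tau` is the strict threshold function.
3. The energy `E = 1 - tau(Sm, k) * tau(q, h)`, restricted to the
   thresholded foreground, is flooded from the markers by a stable
   priority flood (lowest energy first, FIFO within plateaus, 8-connected),
   so with this binary energy the flood reduces to geodesic growth from
   the markers and the boundary ridge decides where touching nuclei split.
4. Small instances are removed and labels canonicalized to 1..N.

The thresholds default to `h = 0.5`, `k = 0.4`. The published description
of this step leaves both "set according to experience", so they are
exposed in `postproc_config()` and the defaults were fixed once against
the ideal-map round-trip property below before any learned model was
evaluated. Each instance's type is then the majority argmax class over
its pixels with background votes excluded, ties broken by summed
probability, and an all-background instance falling back to the strongest
non-background mass.

### Metrics

Evaluation pairs predicted and ground-truth instances at IoU > 0.5 — above
that threshold the pairing is mathematically unique, so greedy matching
equals optimal assignment (asserted against a brute-force oracle in the
tests). From the matching: `DQ = TP / (TP + FP/2 + FN/2)`, `SQ` = mean IoU
over matched pairs, `PQ = DQ * SQ`; the detection score
`Fd = 2TP / (2TP + FP + FN)`; and the per-type score
`Ft = 2(TPt + TNt) / (2(TPt + TNt) + 2FPt + 2FNt + FPd + FNd)`, which
charges both typing and detection errors. How detections should be paired
for `Fd` is not pinned down in the source description (a centroid-radius
rule is also defensible); the IoU matching is reused for consistency.
Multi-image evaluation pools raw counts across images before forming
ratios — the stable convention for small test sets. When ground truth and
prediction are both empty the scores are 1 by convention; 0 when only one
side is empty.

## Synthetic scenes

`generate_scene()` renders rotated, shaded ellipses with class-dependent
hue on a pale noisy background (values 0–255), with seeded, bit-stable
placement. Defaults: 256x256 canvas, semi-axes 6–12 px, class frequencies
(0.70, 0.15, 0.10, 0.05) over K = 4 types — a skew emulating the imbalance
of real nuclei cohorts. Non-touching placement enforces a 2 px clearance;
touching placement lets later ellipses abut earlier ones under first-come
pixel ownership, which keeps the instance partition well defined. The
generator provides exactly what the pipeline needs to be testable — curved
boundaries, touching clusters, imbalance — and deliberately does not
model stain variation, texture, chromatin structure, out-of-focus blur or
annotation noise. Tests passing on these scenes therefore establish the
*mechanics* (encodings, losses, gradients, watershed, metrics) and the
existence of a learnable signal, not performance on real H&E tissue.

## Desk-scale sizes and schedules

The full-size configuration (`base_width = 64`, stages 3-4-6-3) matches
the published architecture; tests and examples run width-reduced models
(`base_width` 2–4, one residual unit per stage) because the package's CPU
tensor engine — tape autodiff over im2col/BLAS convolutions, written
in-package with compiled kernels — is built for correctness and desk-scale
experiments, not GPU-scale training. Training uses Adam with the two-stage
schedule: each stage runs the same settings (the encoder is never frozen),
learning rate 1e-4 dropping to 1e-5 halfway through a stage, batch size 4,
with flips (applied jointly to image and targets, the HV channels changing
sign) and Gaussian/median blur (image only) as augmentation. Desk-scale
runs shorten the stages, may disable the mid-stage drop
(`drop_after = epochs_per_stage`) and use Adam at 2e-3 — the standard
fast-overfit regime for small models on small fixed sets (the published
1e-4 schedule is tuned for 100-epoch runs on real cohorts and
underfits a few-epoch probe).
The valid-padding geometry (270 in, 80 out) is realized as same-padding
interior computation followed by center-cropping to the published output
size — the exact per-layer padding of the original cannot be reconstructed
from its description, and this preserves the published I/O contract; the
crop offset is reported alongside the outputs. Inputs whose size is not a
multiple of 8 are rejected in same mode and center-cropped in valid mode.

Problem sizes used by the shipped checks: the ideal-map round-trip runs
50 scenes of 10 non-touching nuclei at 256x256 and 20 touching-allowed
scenes of 14; the training-signal probe runs 200 optimizer steps on 4
fixed 64x64 patches; the held-out demonstration trains `base_width = 4`
on 64 patches of 6 nuclei and evaluates 16 fresh scenes. These sizes were
chosen once as the smallest that exercise every code path with stable
statistics.

## Known limitations

* The per-layer channel widths, exact refinement-head wiring and
  pretrained initialization of the original design are not recoverable
  from its description; the package documents its choices above and keeps
  them configurable. Published cohort-level scores are not reproducible
  without the original datasets and GPU-scale training, and the package
  does not attempt them.
* The watershed allocates zero-energy ridge bands in flood order; a
  different marker-propagation scheme (e.g. intensity-weighted Voronoi
  growth) assigns those few pixels differently. The tests compare the two
  at the level of recovered instances, where they agree.
* Batch-norm statistics make training-mode losses batch-size dependent;
  eval-mode inference is bit-deterministic for fixed weights and input.
* 16-bit PNG label maps are written by a minimal in-package encoder
  (grayscale, non-interlaced) and read back through standard libpng; NPY
  support covers format version 1.0, the common case.
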