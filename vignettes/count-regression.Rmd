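---
title: "Counting from image-level labels: model, training and refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting from image-level labels: model, training and refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many ecological datasets come with a single integer per image -- the number of
objects of interest that a person once counted -- and nothing else: no boxes,
no points, no masks. Two archetypes drive this package's design. In otolith
micrographs, concentric post-settlement growth rings are counted to age
juvenile fish; the rings are cryptic, overlapping, and essentially impossible
to annotate individually, while the accessory growth centre (AGC) in the
middle contains rings that must *not* be counted. In aerial survey photographs
of hauled-out seals, animals are counted per photograph; the archives are
highly variable in lighting, distance and focal length, and the historical
labels systematically under-report the truth because animals visible in
several overlapping photographs were counted only once.

`deepcount` treats counting as direct regression: a convolutional network maps
the pixels to one continuous number, trained only on image-level labels. The
package implements the full workflow -- synthetic benchmarks, stratified
evaluation design, the regressor and its training protocol, a two-step
refinement loop for noisy labels, and class-activation heatmaps -- so that
every stage can be exercised and tested end to end on a CPU with no external
data.

## The regressor

`build_regressor()` assembles a backbone and a two-layer regression head: the
backbone's pooled features (width $F$) map to 512 neurons (ReLU) and then to a
single continuous count. The head therefore holds
$F \cdot 512 + 512 + 512 + 1$ parameters, and its final layer is
zero-initialised so an untrained model predicts 0 -- a convenient, testable
baseline. No output clamp is applied: predictions are raw reals, and rounding
or clamping at zero is an explicit reporting option (`round_clamp`), never
part of the model. Whether such a transform should precede metric computation
is genuinely ambiguous in practice; keeping raw outputs makes both choices
available and keeps ranking in the refinement loop free of rounding ties.

Because no deep-learning runtime ships in this package's dependency stack,
the convolutional engine is implemented in-package: batched 3x3 convolutions
(im2col + BLAS gemm through RcppArmadillo) with analytic backpropagation,
verified in the test suite against finite differences. The shipped backbone,
`backbone_spec("tiny")`, is a compact four-block network (channels 8/16/32/64,
strides 1/2/2/2, global average pooling, $F = 64$; a `"tiny-wide"` variant
doubles the widths to $F = 96$) intended for 64x64 greyscale inputs. This is
deliberately desk-scale: training runs in tens of seconds per model on one
CPU core. Residual ImageNet-pretrained backbones are not available here --
there are no weights to load and no runtime to run them -- so
`pretrained = TRUE` is rejected with an explanation, and the published
training recipes that assumed pretraining are preserved separately as
`protocol_preset()` values (see below).

The model's parameters are partitioned into three contiguous sections: blocks
1-2, blocks 3-4, and the head. The backbone cut sits at the midpoint of the
blocks; any split consistent with "early / late / head" would do, and the
midpoint is the only choice that needs no extra parameter.

## Loss

Training minimises the Huber loss, averaged over a batch of $n$ images:

$$\mathcal{L}(y, \hat{y}) = \frac{1}{n} \sum_i^n z_i, \qquad
z_i = \begin{cases} 0.5\,(y_i - \hat{y}_i)^2 & \text{if } |y_i - \hat{y}_i| < 1 \\
|y_i - \hat{y}_i| - 0.5 & \text{otherwise.} \end{cases}$$

The quadratic zone (residuals under one count) pushes near-correct
predictions towards exactness; the linear zone caps the gradient magnitude at
$1/n$ per element, so a handful of images with wildly wrong labels -- exactly
what a noisy archive produces -- cannot dominate an update. The switch point
at one count is the natural unit for count data and is kept fixed.

## Training protocol

`run_protocol()` reproduces the two-phase transfer-learning recipe:

1. **Head phase.** Only the two added fully-connected layers train; backbone
   sections 1-2 are frozen (their parameters are bit-identical afterwards,
   which the tests check).
2. **Fine-tune phase.** Everything unfreezes and trains with *discriminative
   learning rates*: the early section at the low end of a range, the head at
   the high end, the middle section at their geometric mean
   (`discriminative_lrs(low, high)`). The geometric mean is the package's
   choice for the unstated middle rate -- learning rates live on a log scale,
   so it is the natural interpolant.

Within each phase the per-section base rate follows a *one-cycle* schedule:
cosine warm-up from `base/25` to the peak over the first 30% of steps, then
cosine annealing to `base/1e4`. Warm-up fraction, dampening factors and the
cosine shape are configurable (`one_cycle_spec()`); the schedule is required
to attain its maximum exactly once and end below its start, and a test scans
a 1,000-step schedule for unimodality. The optimiser is Adam
($\beta = (0.9, 0.99)$, $\varepsilon = 10^{-8}$) with decoupled weight decay
0.01 on weights only -- common defaults, recorded here rather than inherited
from any external framework.

"Best epoch" means **minimum validation loss**: after every epoch the
validation Huber loss is computed on un-augmented images, and the returned
model is the parameter snapshot of the best epoch, not the last. Validation
never sees augmentation because the augmentation policy is attached to the
training dataset only (`set_augmentation()`).

Two protocol presets keep the published recipes verbatim -- otolith: 25 head
epochs at LR 5e-2, then 50 epochs at 9e-7..9e-5, batch 84; seal: 50 epochs at
3e-2, then 50 at 3e-4..3e-2, batch 100. They document the original
configuration and parameterise nothing else in this package; the desk-scale
default (`desk_protocol()`: 3 head epochs at 1e-2, 12 fine-tune epochs at
2e-4..2e-3, batch 64) is tuned for the tiny backbone trained from random
initialisation, where the ultra-low fine-tuning rates appropriate for a
pretrained trunk would barely move the weights.

## Evaluation design

Counts in real archives are right-skewed: images with many objects are rare.
A uniform random test set would barely sample the high counts, precisely
where models fail. `stratified_test_split()` therefore bins images by label
-- equal-width bins over the observed range, closed upper edge so the maximum
label lands in the last bin -- and draws a fixed number per bin. Equal-width
is an assumption (quantile bins would be the alternative); it is simple,
reproducible, and matches binned label histograms of survey archives. The
split is an exact partition, checked by id multiset equality in the tests.

Metrics (`compute_metrics()`) are $R^2$, RMSE and MAE plus totals accounting:
the summed predicted count as a percentage of the summed annotated count, the
quantity a monitoring programme ultimately consumes. $R^2$ is the coefficient
of determination $1 - SS_{res}/SS_{tot}$, *not* squared Pearson correlation;
the two differ for biased predictors and the determination form correctly
penalises a model that, say, halves every count. With zero label variance
$R^2$ is reported as `NA` rather than a number.

## Augmentation that cannot change the label

Every training-time transform must leave the count valid, which rules out
cropping entirely. The policy (`augmentation_policy()`) composes horizontal
flip, small shear (default magnitude 0.06), zoom in `[0.9, 1.1]` with
zero-padding compensation, a multiplicative lighting jitter, and an
aspect-ratio-ignoring squeeze to the target size -- all in a single bilinear
resample. The zoom cap of 10% is matched to the synthetic generator's
placement margin (objects stay 10% of the image width away from the border),
so a zoom-in crop can never cut a counted object out of the frame. The test
suite drives 1,000 augmented clean scenes through an independent
connected-component oracle and requires the count to survive every one.

## Synthetic benchmarks

The package generates its own data so that ground truth is exact and every
downstream contract is testable.

**Dot scenes** (`dot_scene_spec()`, 64x64 by default) emulate the statistical
structure of aerial survey photographs: bright, anti-aliased elliptical
objects with per-object size jitter, rotation and elongation (up to 1.8); a
scene-level scale factor (all animals in one photograph are at a similar
distance) drawn from 4-10% of the image width; smooth background texture;
multiplicative lighting jitter (0.85-1.15); and optional thin bar-shaped
distractor marks that emulate birds and are never counted. When overlap is
disallowed, the scene scale is tapered with the requested count so dense
scenes remain placeable -- which also mirrors reality, where crowded haul-outs
are photographed from farther away. Counts default to 0-30 with a
geometric-decay distribution (`skewed_count_weights()`), reproducing the
scarce-high-counts shape of real archives.

**Ring images** (`ring_image_spec()`, 128x128 by default) emulate otolith
micrographs: a bright AGC disc with no countable rings, surrounded by exactly
the labelled number of concentric rings (a truncated cosine radial profile,
2 px spacing), Gaussian blur, a small random centre offset, and optional
discrete magnification levels standing in for microscope zoom. The renderer
guarantees the rings fit inside the frame or refuses the specification. A
radial-profile peak-count oracle in the tests recovers the label exactly.

**Label noise** (`label_noise_model()`) is *undercount-only*: with some
probability the label becomes `floor(true * f)` with `f` drawn from a
retained-fraction interval. The real noise source -- deduplication across
overlapping photographs -- can only remove counts, so symmetric additive
noise would be the wrong model. Scenes whose scene-level object scale falls
below a threshold are flagged unidentifiable: the stand-in for photographs a
human recounter has to reject, made deterministic so the discard-and-replace
rule is testable. The magnitude of noise in the real archives is not
documented anywhere, so the defaults (corruption probability 0.4, retained
fraction 0.4-0.95) are explicitly configurable guesses, not estimates.

What the generators do *not* emulate: photorealistic appearance, perspective
and viewing-angle geometry, occlusion between animals, focus gradients, and
annotator disagreement. Passing tests therefore demonstrate that the
machinery -- contracts, training dynamics, selection logic, evaluation
arithmetic -- behaves correctly on data with the right statistical shape; they
are not evidence about accuracy on real photographs.

## The two-step refinement loop

When most labels are noisy undercounts, relabelling everything defeats the
purpose of automation. The refinement loop spends a fixed relabelling budget
where the model disagrees most with the archive:

1. Train a step-1 model on the clean (but biased) subset.
2. Predict the whole noisy pool and rank by the signed residual
   `predicted - noisy_label` (`rank_discrepancies()`); raw predictions are
   used because rounding would create mass ties, and the residual is taken
   against the *noisy* label, since that is the only label that exists at
   this point.
3. Select the `k_over` most over-estimated and `k_under` most under-estimated
   images (default 50 + 50). An over-estimate against an undercounted label
   is exactly the signature of label noise; an under-estimate flags images
   the model cannot yet handle (typically high counts). Unidentifiable
   images are discarded and replaced by the next-worst record *in the same
   tail*, preserving the over/under balance; cross-tail replacement would
   skew the budget towards whichever tail happens to be cleaner.
4. Relabel the selection via the oracle, merge with the clean subset,
   re-split 80/20 (uniform random; the split is not stratified by origin),
   and fine-tune the whole network (`refine()`).

The selection logic is deterministic and is checked against a brute-force
enumeration on a thousand random pools. The package runs one refinement
round; iterating further is possible in principle but out of scope.

## Class-activation heatmaps

`compute_cam()` produces gradient-weighted CAMs adapted to a scalar
regression output: channel weights are the spatially averaged gradients of
the predicted count with respect to the last convolutional block's
activations. With a two-layer head on global average pooling the gradient is
spatially constant and has a closed form through the head, so the
computation is exact and cheap. The weighted activation map is rectified
before normalisation -- only regions that *raise* the count are shown, which
is the interpretation of "contributed to the prediction" that matches a
counting task -- then min-max normalised after bilinear upsampling, so a
non-constant heatmap always attains both 0 and 1, and a degenerate
(constant) map is defined as all-zero. Plain CAM would require a single
linear layer over pooled features; the extra hidden layer is why the
gradient-weighted variant is used.

Heatmaps are qualitative. The tests quantify only a weak property: for a
trained model, mean heat inside the generator's ground-truth object masks
exceeds mean heat outside in at least 80% of scenes. Per-object localisation
is explicitly not evaluated -- image-level counts cannot support it.

## Problem sizes and numerical choices

The shipped experiment sizes are chosen so the full test suite trains real
models in minutes on one CPU core: the learning check uses 600 training /
150 validation / 120 stratified-test images at 64x64 with counts 0-30 across
ten seeds; the refinement check uses a 450-image clean subset capped at 40%
of the count range, a 450-image noisy pool, an 80-image stratified test set,
and a 50 + 50 selection, again across ten seeds. Improvement is measured as
RMSE on the test labels above the clean cap -- the bins the step-1 model has
never seen -- together with the predicted/annotated totals percentage.

Other numerical choices, gathered in one place: train/validation splits use
`floor(fraction * n)` for the training size (deterministic tie handling);
stage seeds are derived from one global seed by fixed offsets, so a single
integer reproduces an entire experiment including split membership and
selection files; all generators restore the caller's RNG state; convolutions
run in double precision; and the Adam state is *not* carried across phases
(each phase is a fresh optimisation problem with its own schedule).

## Known limitations

The tiny backbone saturates well below the capacity of a pretrained residual
network, and 64x64 renders cannot represent objects at the smallest real
scales -- both are the price of CPU-scale reproducibility. The synthetic
scenes lack the appearance diversity that makes real archives hard, so
absolute metric values here say nothing about real-data accuracy; the
package's claims are about the *relative* behaviour of its components (a
trained model beats the mean predictor; refinement recovers under-served
high counts; selection equals brute force). Equal-width binning can produce
sparsely populated bins on extremely skewed label distributions, in which
case the stratified split correctly refuses and the bin count must be
lowered. Undercount-only noise is faithful to deduplication but will not
model annotator over-counting.
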