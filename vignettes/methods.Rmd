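---
title: "Whole-volume organ-at-risk segmentation: models, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-volume organ-at-risk segmentation: models, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oarseg)
```

## The problem

In breast-cancer radiotherapy planning, the breasts and the heart are
contoured on the planning CT as organs-at-risk (OARs). Manual contouring is
slow and shows substantial inter-observer variability, especially for the
breast, whose boundary against the surrounding fat is diffuse. `oarseg`
implements a fully convolutional 3-D segmentation pipeline built around a
residual multi-resolution network that processes a whole working-resolution
volume in a single forward pass, together with the complete machinery
needed to train and evaluate it: spacing harmonisation, patch samplers,
a Jaccard training objective, tournament selection over random
initialisations, clinical post-processing, and surface-distance evaluation
metrics with paired-test model comparison.

Because clinical CT cohorts with curated structure sets cannot be shipped,
the package includes a seeded thorax phantom generator. Every stage of the
pipeline is exercised end-to-end on these phantoms.

## The bib-shaped network

The whole-volume network is a grid of residual blocks, wider at full
resolution and narrower at depth (hence "bib"):

* An **encoder column**: residual blocks per resolution level, with
  stride-2 (2,2,2) convolutions between levels and filter width doubling
  after each pooling.
* **Lateral rows** at every level, fed additively by the same-level
  encoder output and by strided/transposed projections of the adjacent
  levels' encoder outputs, so features are processed at — and exchanged
  between — all resolution scales.
* A **decoder column** that walks back to full resolution with stride-2
  transpose convolutions, concatenating the lateral output of each level
  before a merge block and further residual blocks.

The atomic unit is the convolutional block — dropout, 3x3x3 padded
convolution, PReLU, batch normalisation, in that order — and a residual
block is two such blocks plus an additive identity skip. The head is a
1x1x1 convolution with an independent sigmoid per organ, so multi-organ
outputs are multi-label maps; the three thoracic OARs are spatially
disjoint, so no exclusive softmax is needed. Padding keeps the output's
spatial shape equal to the input's; inputs not divisible by
`2^(levels - 1)` are zero-padded symmetrically and cropped back.

Two printed properties pin the default configuration jointly: the network
has about 7.5 million trainable parameters, and a neuron in the deepest
encoder layer sees a receptive field of 484 voxels per axis — enough to
cover an entire working-resolution thorax. With the composition rule that
a kernel-`k` layer at cumulative stride `S` widens the field by
`(k - 1) * S`, the default encoder plan — residual blocks (1, 2, 2, 3, 5)
over five levels, a kernel-1 stem — gives exactly
`1 + 4 * 117 + 15 = 484`, and the full block plan (lateral rows
(3, 3, 3, 1, 1), decoder (1, 1, 1, 1), 8 base filters, growth factor 2)
counts 7,500,833 parameters:

```{r anchors}
receptive_field(bibnet_config())
set.seed(1)
count_parameters(build_bibnet(bibnet_config()))
```

Design choices where the architecture family leaves freedom, and why:

* **Merges**: additive inside residual blocks and for cross-level lateral
  inputs (after projection); channel concatenation for the encoder-to-
  decoder skips at equal resolution. This follows the U-Net and ResNet
  ancestry of the design.
* **Block order**: dropout, convolution, activation, normalisation — kept
  exactly as specified for the convolutional block even though
  activation-after-normalisation is more common.
* **PReLU** has one learnable slope per channel, initialised at 0.25.
* **Initialisation**: seeded He-uniform over `fan_in = k^3 * C_in`; the
  head's bias starts at -2 so the initial foreground probability (~0.12)
  reflects that organs occupy a small volume fraction, which conditions
  the soft overlap loss at the start of training.
* **Output head**: independent sigmoids (multi-label), see above.
* **Precision**: convolution arithmetic runs in single precision (the
  GEMM operands are large and memory-bound); everything else is double.

## The valid-convolution U-Net baseline

The comparison network is a fixed 3-level U-Net with two unpadded 3x3x3
convolutions and a max-pooling per encoder level (filters 32/32, 64/128,
256/256), nearest-neighbour upsampling and two convolutions per decoder
level (128/128, 64/64), ReLU activations, centre-cropped skip
concatenations and a sigmoid head. Because every convolution is valid,
each axis shrinks by 40 voxels between input and output, and inference
tiles the volume with patches whose output windows abut exactly. Tiled
and single-pass outputs agree identically on the covered interior — the
defining property of valid-convolution patch inference — and the
uncovered border is flagged `NA` rather than imputed.

The minimum admissible input extent works out to 44 voxels per axis, with
extents congruent to 0 mod 4 so the two pooling grids align. A symmetric
valid-convolution analysis cannot produce every input size (an input of
68 yields an output of 28 per axis under this arithmetic); the
`unet3_out_extent()` rule in the package is the single source of truth
for its shapes and is tested against the symbolic arithmetic.

## Objectives and metrics

Training minimises the **soft Jaccard loss**
`J = 1 - (sum(p*y) + eps) / (sum(p) + sum(y) - sum(p*y) + eps)` with
`eps = 1e-5` to avoid 0/0 on empty structures; the smoothing constant is a
numerical guard, not a tunable. Validation ranking and reported scores use
the **Dice coefficient**; for hard masks the Jaccard ratio `r` and Dice
`DSC` obey `r = DSC / (2 - DSC)`, which the suite checks on random mask
pairs. Per-voxel binary accuracy is provided for reference but is
uninformative on background-dominated volumes.

Surface metrics operate on the world coordinates of boundary-voxel
centres, where a mask voxel is boundary when at least one 6-neighbour is
background (outside the grid counts as background). The **RMS surface
distance** is directed — prediction surface to ground-truth surface — as
its defining formula is; the symmetrised mean distance is reported
alongside for information. The **Hausdorff distance** is the symmetric
max-min distance. Nearest-distance searches use exhaustive minimisation
in compiled code, and the distance field used by the shell sampler is an
exact separable Euclidean distance transform under anisotropic spacing;
both are tested against plain-R brute force to 1e-6 mm.

Both-empty mask pairs yield flagged undefined metrics (`NaN`), never a
silent 0 or 1, mirroring how failed segmentations are excluded — per
organ, with an explicit reason — from cohort summaries, which report the
median per organ precisely because one failure can dominate a mean.

## Preprocessing

Volumes are harmonised by trilinear resampling to a common spacing
(typically 1.17 mm in-plane, 3 mm slices) and then downsampled by two in
the axial plane to 2.34 mm for whole-volume training. Numerical
conventions the resampling contract leaves open are fixed as follows:

* Output shape is `ceiling(shape * spacing / target)` — never discarding
  physical extent.
* Out-of-domain samples use edge-value extension, avoiding spurious air
  borders inside the body.
* Masks are interpolated trilinearly like the images and re-binarised at
  0.5.
* The 8-bit quantisation window defaults to (-1024, 1024) HU; values are
  clipped and rounded half away from zero.

## Patch samplers

Four samplers generate training patches: an entropy sampler that rejects
patches whose 256-bin 8-bit histogram entropy is at or below a threshold
(default 2 bits) to avoid featureless air; two shell samplers whose patch
centres lie within 20 or 40 mm (Euclidean, anisotropic spacing) of a
ground-truth surface; and a mask sampler requiring intersection with the
ground truth. Admissibility is decided on the patch centre voxel. The
composite sampler mixes them with configurable weights (equal by
default). The entropy threshold and the mixing weights are declared
defaults, not estimates. Rejection sampling has a 10,000-draw budget
before raising a sampler-exhausted error.

## Training

Optimisation is Nesterov-Adam (Nadam) on the soft Jaccard loss, with the
bias-corrected look-ahead recurrence

```
m <- b1*m + (1-b1)*g ;  v <- b2*v + (1-b2)*g^2
w <- w - lr * (b1*m/(1-b1^(t+1)) + (1-b1)*g/(1-b1^t)) / (sqrt(v/(1-b2^t)) + eps)
```

using the canonical `b1 = 0.9`, `b2 = 0.999`, `eps = 1e-8` (only the
learning rate is scheduled). The learning rate starts at 1e-2 and decays
linearly to 1e-5 over the planned epochs, clamping thereafter. The suite
verifies the recurrence against an independent scalar re-derivation.

**Tournament selection**: eight networks are initialised with independent
seeds and trained concurrently-in-schedule; the worse half by validation
loss is dropped at epochs 20, 40 and 80, and the single survivor
continues until its validation loss stops improving. "Until convergence"
is realised as early stopping with a patience of 10 epochs, and the best
validation checkpoint is returned. Validation ranking uses the Dice loss
(1 - hard Dice) while back-propagation uses the Jaccard loss; the
multi-organ loss is the unweighted mean of per-channel Jaccard losses.
Each network draws its training batches from an independent seeded
stream; whether the population should share one batch sequence is left
open by the procedure's description, and independent streams are the
natural choice for de-correlated initialisation tournaments. The pure
selection rule (`tournament_select()`) is separated from the loop so it
can be verified against sort-and-keep on stubbed loss traces.

Batch-normalisation statistics are computed per volume during training
(full-image batches at this scale are 1-2 samples) and running averages
(momentum 0.1) are used at inference.

## Inference and post-processing

Whole-volume networks run once per volume in evaluation mode (dropout
off, running statistics), returning per-organ probability maps at the
input shape. The clinical post-processing chain is: trilinear upsampling
of the probability map to the CT geometry, Gaussian smoothing, 0.5
thresholding, and retention of the largest connected component.
Smoothing is applied to the probabilities *before* binarisation — the
chain's description leaves the order open, and smoothing probabilities
avoids re-binarisation artifacts. Defaults: sigma 1.5 mm (spacing-aware,
separable, replicated edges), threshold 0.5, 26-connectivity. Organs are
post-processed independently; overlaps between organ masks are reported,
not resolved. An empty post-threshold mask is returned flagged so that
evaluation can exclude it explicitly.

## Statistics

Models are compared with a classical paired two-tailed t test per organ
on Dice and on RMS surface distance, with the significance level
Bonferroni-adjusted for the three model pairs (`0.05 / 3 = 0.0167`); raw
p-values are always reported alongside. Degenerate comparisons (all-zero
differences) are flagged, not scored. The suite checks the test's type-I
rate on 500 seeded null simulations at n = 20.

## The phantom generator

The phantom emulates the segmentation-relevant geometry of a thorax CT at
working resolution: an ellipsoidal fat-intensity trunk on an air
background, two low-intensity lung ellipsoids, a heart ellipsoid between
them, and two anterior breast blobs whose union with the trunk forms the
body — so organ masks are inside the body by construction. Intensities
are HU-like class means (air -1000, lung -700, fat -100, soft tissue 40)
with additive Gaussian noise (default sd 20), chosen so intensity
windowing and the entropy sampler are exercised realistically; they are
configuration defaults, not claims about tissue physics. Default grids
are 64 x 64 x 32 voxels at (2.34, 2.34, 3.0) mm — a scaled-down version
of the working resolution that trains on one CPU. Cohorts jitter each
organ's radii multiplicatively (±8%) and centres additively (±4 mm) from
seeded uniform draws; every case is reproducible from (spec, seed, index).

What the phantoms deliberately do **not** model: reconstruction kernels,
beam hardening, metal or contrast artifacts, arm-position variation,
breast-boundary diffuseness, or anatomical correlation between organs.
Tests passing on phantoms therefore demonstrate that the pipeline's
machinery is correct and trainable, not that clinical-grade accuracy
would be reached on patient data.

## Problem sizes and numerical choices in the test suite

The suite runs the full pipeline at deliberately small scale, chosen once
as CPU-friendly study conditions: engine gradient checks on 4^3 volumes
against central finite differences (with the step size matched to the
kernels' single-precision forward noise); oracle equivalence of all
metrics on 100 random mask pairs up to 16^3; patchwise-equals-full-pass
on a 48 x 48 x 44 volume with 44^3 patches; and a learning proxy in
which a reduced two-level, eight-filter network is trained on eight
64 x 64 x 32 phantoms to a training Dice of at least 0.90 on all three
organs within 300 Nesterov-Adam steps under the standard 1e-2 to 1e-5
linear decay.

The proxy trains on whole volumes (the sampler patch covers the full
grid), matching the network's single-pass full-image contract. This
choice matters for two reasons observed while characterising the
pipeline. First, spatial context: the two breasts are locally identical,
so distinguishing left from right requires in-plane position cues that
xy-cropped patches destroy. Second, normalisation statistics: batch-norm
statistics gathered from small organ-biased patches differ from
whole-volume statistics, so a patch-trained network evaluates worse on
full volumes than its training loss suggests; whole-volume batches make
training and inference statistics agree, and the decaying learning rate
then freezes the running averages that evaluation-mode inference uses.
A constant high learning rate, by contrast, keeps the feature statistics
drifting indefinitely and the running averages never converge — the
linear decay is not incidental but what makes running-statistics
inference consistent. The reduced configuration disables dropout (the
0.5 default is the full-scale regularisation level; a 300-step
overfitting exercise needs none) and places its processing depth at the
cheap half-resolution level.

Training Dice per organ is the mean over the training phantoms, the
conventional training-set summary. The reduced configuration's block
plan is not arbitrary: the cohort's two breasts are exact mirror images
of one another (the radius and centre jitters are drawn once per case
and mirrored), so telling left from right is a purely positional task.
With too shallow a half-resolution column the receptive field covers
only part of the volume, and a breast channel can converge to the union
of both breasts (case Dice 2/3) and saturate there; with the default
reduced plan the effective receptive field spans the whole volume and
both breast channels separate cleanly. This mirrors the design argument
for the full-scale network, whose encoder receptive field covers an
entire working-resolution thorax. The training loop also clips the
global gradient norm at 5 before the optimizer update, a robustness
guard for the high-learning-rate phase of the schedule.

## Known limitations

* The engine is CPU-only, double precision, and optimised for clarity
  and testability; full-scale (256 x 256 x 128) training is out of reach
  on one CPU and is not attempted anywhere in the package.
* Batch normalisation uses per-volume statistics (see above); very small
  structures in very large volumes may prefer synchronised multi-volume
  statistics.
* The U-Net baseline's z-axis pooling is isotropic; input sizes must be
  congruent to 0 mod 4 per axis.
* DICOM and DICOM-RT STRUCT are out of scope; I/O is NIfTI with a JSON
  organ-to-filename sidecar.
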