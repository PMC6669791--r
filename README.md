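# oarseg

Whole-volume 3-D segmentation of thoracic organs-at-risk (left breast,
right breast, heart) in CT-like volumes, for radiotherapy treatment
planning research.

Manual OAR contouring on a planning CT takes tens of minutes per patient
and varies between observers, particularly for the breast, whose boundary
against surrounding fat is diffuse. `oarseg` implements, in R, a complete
deep-segmentation pipeline built around a residual multi-resolution
network — a "bib"-shaped grid of residual blocks — that segments an
entire working-resolution volume in a single forward pass, plus the
3-level valid-convolution U-Net baseline it is compared against, and all
of the surrounding machinery:

* **Data model and I/O**: `image_grid` / `structure_set` types, NIfTI
  volumes with a JSON organ-to-filename sidecar (`read_image`,
  `write_structure_set`, ...).
* **Phantoms**: a seeded thorax phantom generator (`phantom_spec`,
  `generate_cohort`) so the full pipeline runs end-to-end with no
  external data.
* **Preprocessing**: trilinear spacing harmonisation (`resample_trilinear`),
  axial downsampling, mask resampling, 8-bit intensity windowing.
* **Models**: `build_bibnet` (shape-preserving, padded; ~7.5 M parameters
  and a 484-voxel-per-axis encoder receptive field in the default
  configuration) and `build_unet3` (valid convolutions, patch-wise
  inference via `infer_patchwise`), with analytic `count_parameters` and
  `receptive_field`. The 3-D conv-net engine (forward, backprop,
  Nesterov-Adam) is implemented in the package with RcppArmadillo
  kernels.
* **Objectives and metrics**: soft Jaccard loss, Dice, directed RMS
  surface distance, Hausdorff distance — all tested against brute-force
  oracles.
* **Samplers**: entropy / 20 mm and 40 mm shell / mask patch samplers and
  their weighted composite.
* **Training**: Nesterov-Adam with a linear 1e-2 to 1e-5 learning-rate
  decay and tournament selection (8 -> 4 -> 2 -> 1 at epochs 20/40/80)
  over random initialisations (`tournament_train`).
* **Inference and post-processing**: full-image probability maps,
  Gaussian smoothing, thresholding, largest connected component
  (`postprocess`).
* **Evaluation**: per-case/per-organ metric reports with explicit
  exclusions and median summaries (`evaluate_cohort`), paired two-tailed
  t tests with Bonferroni-adjusted significance (`compare_models`).

The model core in one line: organ probability maps `p = f_theta(x)` are
trained by minimising the soft Jaccard loss
`J = 1 - (sum(p y) + eps) / (sum(p) + sum(y) - sum(p y) + eps)`
and evaluated with `DSC = 2|X∩Y| / (|X|+|Y|)`, the directed RMS
surface distance and the Hausdorff distance.

## Worked example

```r
library(oarseg)

# two anchors of the default whole-volume architecture
receptive_field(bibnet_config())
#> [1] 484 484 484
set.seed(1)
net <- build_bibnet(bibnet_config())
count_parameters(net)
#> [1] 7500833

# preprocessing chain: clinic resolution -> working resolution
g <- image_grid(array(rnorm(16 * 16 * 8), c(16, 16, 8)),
                spacing = c(0.98, 1.27, 2.5))
downsample_axial(resample_trilinear(g, c(1.17, 1.17, 3.0)), 2)$spacing
#> [1] 2.34 2.34 3.00

# Bonferroni-adjusted level for three model comparisons
bonferroni_alpha(0.05, 3)
#> [1] 0.01666667
```

The receptive field (484 voxels per axis for the deepest encoder layer)
says a single neuron at the bottom of the encoder can see an entire
working-resolution thorax volume, which is what makes single-pass
whole-volume segmentation viable; the parameter count is the network's
capacity at the default block plan; 2.34 mm is the in-plane working
resolution after harmonisation and 2x axial downsampling.

A small end-to-end run on phantoms (generation, tournament training,
inference, post-processing, evaluation):

```r
res <- run_pipeline(default_run_config(seed = 1))
summary(res$report)   # per-organ median/mean Dice and distances
```

A thin CLI wrapping the same functions is installed with the package
(`system.file("cli", "oarseg", package = "oarseg")`), with subcommands
`generate-phantoms`, `preprocess`, `pipeline`, `evaluate`, `compare`.

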