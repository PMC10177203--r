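---
title: "Methods: frozen-CNN features, grouped nested CV, and crop-vote testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frozen-CNN features, grouped nested CV, and crop-vote testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

histocad implements a computer-aided pathology pipeline for binary
classification of hematoxylin-and-eosin (H&E) histology images — benign
versus malignant — in archives where images are nested within *cases*
(one histological slide, i.e. one patient, contributing many images with a
single shared label). The canonical use case is a canine mammary tumour
archive of 1024 x 768 JPEG images at 400x magnification, with 44 cases and
roughly 24 images each; the reader also understands the BreakHis human
breast-cancer layout.

The pipeline has four stages:

1. **Augmentation.** Two training strategies. *Base*: resize the shorter
   edge to 512 px, take a uniform random square crop at the backbone's
   input size (224 px for VGG16, 299 for Inception v3, 380 for
   EfficientNet-B4), rotate by a random multiple of 90 degrees, and flip
   vertically with probability 1/2. *Advanced*: take a crop whose area is
   a uniform fraction in [0.08, 1] of the image with aspect ratio
   log-uniform in [3/4, 4/3], resize it to the input square, apply the same
   rotation/flip, then jitter brightness, contrast and saturation each by
   an independent factor in [0.8, 1.2]. Images are then normalized with the
   ImageNet channel statistics (mean 0.485/0.456/0.406, sd
   0.229/0.224/0.225 on the unit scale).
2. **Frozen feature extraction.** A pretrained CNN is used purely as a
   feature extractor: intermediate convolutional maps are tapped at named
   stages, each map is reduced by global average pooling (GAP — the spatial
   mean, one value per channel), and the pooled vectors are concatenated.
   For VGG16 the taps are the five block outputs just before each
   max-pooling layer (64 + 128 + 256 + 512 + 512 = 1472 features). The tap
   points for Inception v3 (after the first two convolutional and first two
   inception blocks) and EfficientNet-B4 (before every channel increase)
   are recorded in a versioned tap registry; their exact layer names are
   resolved against the standard published architecture definitions and
   flagged there as an interpretation of the verbal rule.
3. **Classification.** Features are standard-scaled with statistics of the
   *training* rows of the current split only. Four families: linear SVM,
   degree-3 polynomial SVM, RBF SVM, and stochastic gradient boosting
   (SGB) over depth-limited trees with per-iteration row subsampling. The
   polynomial and RBF kernels go through a Nystroem low-rank map (below)
   followed by a linear SVM in the mapped space.
4. **Evaluation.** Patient-grouped nested 5-fold cross-validation: the
   outer folds partition *cases*, never images, so no slide contributes to
   both sides of any split; within each outer training set a second
   grouped 5-fold split drives random-search hyperparameter tuning. Test
   images are classified either from their single center crop or by
   majority vote over ten crops (center + four corners + the horizontal
   flips of those five). Reports carry per-fold image-level accuracies with
   mean and sample sd, and pooled PPV/NPV with malignant as the positive
   class.

## Why grouping is the load-bearing choice

Slides differ in staining, sectioning and acquisition; images from one
slide share that signature. An image-level split lets a classifier
recognise the slide rather than the lesion, inflating accuracy with
information that does not generalise to new patients. The package makes
the grouped split the only default; an image-level mode exists solely to
*demonstrate* the inflation (`grouping = "image"`), and the test suite
asserts that on a fixture with zero class effect and a strong per-case
stain confound the ungrouped run scores high while the grouped run stays
at chance.

## The Nystroem map

For kernel k and landmark rows L (a seeded subsample of the training
rows), the map is

> phi(x) = k(x, L) U diag(lambda)^(-1/2),

where k(L, L) = U diag(lambda) U' is the eigendecomposition of the
landmark block (eigenvalues below 1e-12 of the largest are dropped). Then
phi(x) phi(y)' approximates k(x, y), exactly when the landmark set is the
whole sample and the Gram matrix has full rank — which is how the tests
pin it against an exact kernel computed by brute force. Landmarks are
always drawn from the training side of the current split, so the map can
never see test rows; a perturbation test asserts this mechanically.

Kernel parameterization: RBF `exp(-gamma ||x - y||^2)`; polynomial
`(gamma <x, y> + 1)^3`.

## The stub backbone

Pretrained VGG16/Inception/EfficientNet weights are multi-hundred-megabyte
artifacts that cannot ship with the package, so the backbone module also
provides a *stub*: a frozen three-stage CNN with seeded random
He-initialized 3x3 kernels, ReLU, 2x2 mean pooling between stages, taps
after every stage, and the same GAP-and-concatenate readout (default
widths 8/16/32, features F = 56, input 96 px). Random frozen convolutions
are honest texture/colour summarizers — enough for the statistical
structure of the synthetic fixtures — and they exercise every downstream
contract (dimension bookkeeping, determinism, scaling, leakage control)
identically to a pretrained extractor. Requesting a pretrained backbone
without weights fails with an explicit instruction to use the stub. The
named architectures remain specifiable so their feature dimensions and
input sizes are still checked (VGG16 -> 1472).

## The synthetic fixture generator

The generator emulates exactly the statistical features the pipeline is
sensitive to, and nothing else:

- class-dependent texture: nucleus count per image is Poisson with a
  class-specific rate; nuclei are ellipses with truncated-normal radii,
  uniform positions and orientations, drawn in a hematoxylin-like purple
  on an eosin-like pink background;
- case structure: images are nested in single-label case directories in
  the same layout the archive reader consumes;
- case-level appearance shifts: each case has one RGB tint drawn with a
  configurable sd, emulating slide-to-slide staining variability — the
  confound that makes grouped splitting consequential;
- pixel noise: independent Gaussian, sd 3 on the 8-bit scale, which
  prevents degenerate constant features.

Defaults are the package's reference conditions: 20 cases per class, 8
images per case, 96 x 96 px, nucleus rates 20 (benign) versus 120
(malignant), nucleus radius 3 +/- 0.8 px, stain shift sd 8. At that radius
the two classes cover roughly 6% versus 30% of the image with nucleus
pixels, a strong but not degenerate effect. Two derived fixtures are fixed
once for the property checks: a *null* fixture with both rates at 70 (the
midpoint of the separable pair) for chance-level control, and a *confound*
fixture with both rates at 60 and stain shift sd 35 for the leakage
demonstration. The confound sd was set by an independent criterion — the
per-case tint must dominate within-case texture variation so that case
identity is recoverable from the features (checked as 1-NN case
identification) — because a "strong confound" that does not identify cases
would demonstrate nothing. 96 px with the stub keeps a full nested-CV
experiment (320 images, feature extraction included) in the low minutes on
one CPU; the generator also produces 1024 x 768 to mimic the real archive.

What passing these tests does *not* show: performance on real H&E tissue.
The generator has no tissue morphology, no stain co-localisation, no focus
or compression artifacts; it validates the machinery (leakage control,
determinism, contracts), not diagnostic accuracy. Reproducing the
published-scale accuracies requires the external image archives and
pretrained weights and is explicitly out of scope.

## Numerical and design choices

- "Resize to 512 px" is read as *shorter edge* 512 with aspect preserved
  (the archive's images are non-square); bilinear interpolation with
  half-pixel-centre mapping throughout.
- Aspect ratio in the advanced crop is sampled log-uniformly over
  [3/4, 4/3], matching the standard random-resized-crop procedure the
  strategy mirrors; crop dimensions are rounded *up* and clamped to the
  frame so the realized area fraction provably stays inside the configured
  range on an integer pixel grid.
- Advanced-strategy order is fixed: crop -> resize -> rotate -> flip ->
  brightness -> contrast -> saturation. Contrast scales about the mean
  luminance (0.299 R + 0.587 G + 0.114 B); saturation scaling uses the
  HSV identity c' = V + f (c - V) with V the per-pixel channel maximum.
- The scaler uses population (1/n) statistics; zero-variance dimensions
  get scale 1, mapping them to exactly zero on the training rows.
- Ten is even, so ten-crop voting needs a tie-break: a 5-5 vote goes to
  the side with the larger absolute summed decision score, and an exactly
  zero sum resolves to malignant (favouring sensitivity). Single-crop
  labels use score > 0 = malignant.
- Inner folds are grouped by case exactly like the outer folds; the
  spec of the published procedure is silent here, and consistency with the
  outer leakage rule is the only defensible default.
- The sd reported with each accuracy is the sample sd (ddof 1) across the
  outer folds.
- Fold dealing is per-label round-robin over seed-shuffled cases, so fold
  label counts differ by at most one (44 cases at k = 5 deal as
  9/9/9/9/8).
- Hyperparameter search spaces (see `classifier_spec()`) are the package's
  own choices — the reference procedure mandates random search but not a
  grid — and are echoed into every report. The reference property runs use
  10 random-search draws per outer fold; the linear family has a single
  tunable parameter and saturates quickly, and the package default of 20
  remains for real experiments.
- Determinism: one master seed fans out via a hash (`derive_seed()`) to
  the fold plan, every augmentation draw (keyed by image id and replicate,
  so features never depend on fold membership or processing order),
  Nystroem landmarks, search draws and boosting subsampling. Identical
  configuration and seed reproduce reports byte for byte.
- Tuning validates on the center-crop feature of each inner-validation
  image — the deterministic test-time view — never on augmented
  replicates of validation images.

## Known limitations

- No probability calibration, ROC analysis, or multi-class subtyping;
  accuracy, PPV and NPV are the reported metrics, malignant positive.
- Pretrained backbones require external weights; the package ships the
  contract (taps, dimensions, sizes) but not the forward pass weights.
- The Inception v3 and EfficientNet-B4 tap registries are best-effort
  resolutions of verbal descriptions and are flagged as interpretations.
- The boosting learning rate is constant; no shrinkage schedule.
- Class balance is handled only via optional inverse-frequency weights
  (`class_weights = "balanced"`), off by default.
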