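---
title: "Estimating lettuce growth traits from top-view images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lettuce growth traits from top-view images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lactuca` estimates three growth-related traits of greenhouse lettuce —
leaf fresh weight (LFW, g), leaf dry weight (LDW, g) and leaf area
(LA, cm²) — nondestructively from nadir RGB images, and compares the
convolutional approach against the classical image-feature and depth-based
pipelines. This vignette explains the models, the synthetic data that makes
the whole pipeline testable, and the design decisions a maintainer should
know about.

## The estimation problem

Destructive trait measurement (balance, leaf-area meter, oven drying) ends
the plant's life; image-based estimation replaces it. Three families of
estimators are implemented:

1. **Multi-output convolutional regressor** (`train_cnn()`): a
   128×128×3 image is mapped directly to (LFW, LDW, LA). Five 5×5
   convolutional layers with 32, 64, 128, 216 and 512 kernels, 1-px zero
   padding on the second and third layers only, 2×2 stride-2 *average*
   pooling after the first four, dropout (rate 0.5) on the flattened
   1×1×512 map, and a single fully connected layer with three outputs. The
   padding placement is the unique choice that keeps every pooled
   feature-map side integral (`layer_shape_plan()` machine-checks this and
   rejects any configuration that would hit an odd side or a map smaller
   than the kernel).
2. **Shallow regressors on handcrafted features** (`fit_baseline()`): SVR
   (radial kernel) and random forest on the 92 descriptors of
   `extract_features()` — mean and standard deviation of 15 colour
   components (RGB, HSV, CIE L\*a\*b\*, YCrCb, HSI), GLCM contrast /
   correlation / energy / homogeneity for each component, plus plant area
   and perimeter — screened per trait by Pearson correlation
   (`pearson_screen()`, default |r| ≥ 0.65). One single-output model per
   trait.
3. **Structural linear models from depth** (`fit_lr()`): superpixel
   segmentation of the depth map (`segment_depth()`), then projected area
   PA (pixel count), mean canopy height H = sensor height − mean plant
   depth, and digital volume V = PA·H, each used as the sole predictor of
   each trait (LR-PA, LR-H, LR-V).

Accuracy is reported as R² against the 1:1 line,
`1 − Σ(aᵢ−pᵢ)²/Σ(aᵢ−ā)²` (not squared correlation, so it can be
negative), and NRMSE = 100·RMSE/mean(a) in percent. The mean normalizer
matches the magnitude conventions of the comparison grid; range and sd
normalization are available (`nrmse(mode=)`). Every report row satisfies
the identity R² = 1 − (NRMSE/100)²·mean(a)²/var(a) (population variance),
which the tests assert.

## Training protocol

SGD with momentum (default 0.9), initial learning rate 0.001 dropped by a
factor of 0.1 every 20 epochs, mini-batch 128 (the desk-scale benchmark
below uses 32), up to 300 epochs; the weights with the best validation
loss are retained. The loss is mean squared error summed over the three
*standardized* outputs — per-trait training-set mean/sd scaling stops the
cm² scale of LA from dominating the gram-scale weights; predictions are
de-standardized and clamped at zero (with a logged count).

Numerical choices that are not part of the printed protocol:

- **Activation / loss**: ReLU after every convolution; MSE (both standard
  for this architecture family).
- **Input centring**: images enter as values in [0, 1] and are zero-centred
  with the training-set mean (stored in the checkpoint). All-positive
  inputs give badly correlated first-layer gradients at a fixed learning
  rate; the variance is deliberately left unscaled so the update magnitude
  stays matched to the schedule.
- **Initialization**: seeded He fan-in draws, then a layer-wise variance
  calibration on a 16-image batch so every pre-activation has standard
  deviation `init_gain` (default 0.2). Average pooling otherwise shrinks
  the forward signal by roughly half per stage, leaving the regression
  head too little gradient to converge within a short epoch budget;
  calibrating much higher than ≈0.3, however, over-amplifies the first
  layer on background-dominated frames and destabilizes the fixed 0.001
  learning rate. 0.2 sits comfortably inside the stable range and was
  fixed once.
- **Dropout placement**: on the flattened features before the fully
  connected layer (the only unambiguous single location); inverted
  dropout, so prediction needs no rescaling.
- **Determinism**: init, shuffling and dropout all draw from one seeded
  generator in the compiled trainer; two runs with the same seed are
  bit-identical on the same platform.

## Synthetic scenes and what they do (not) show

No image corpus ships with the package; `render_plant()` /
`generate_dataset()` create top-view rosette scenes with known ground
truth so that every stage is testable end to end:

- **Geometry**: leaves are lobed ellipses placed on a golden-angle spiral,
  with leaf count and mean size increasing linearly in expectation across
  the seven weekly sessions; per-leaf area is computed by polar quadrature
  *before* rasterization, so LA is exact irrespective of the pixel grid.
  Occlusion only hides area: total LA ≥ visible projected area by
  construction.
- **Allometry**: LFW = α·LA^β·exp(ε), ε ~ N(0, 0.08²), with α = 0.035
  g·cm^(−2β) and β = 1.1, chosen once so a mature stage-7 plant lands at
  LFW of order 10² g; LDW is a cultivar dry-matter fraction (4.5–5.5%) of
  LFW with its own 8% log-normal noise. A log–log regression over
  generated plants recovers β within sampling error (tested).
- **Cultivars**: two flat-leaf morphologies and one curled (stronger
  boundary lobing, a raised sinusoidal rim, and a compressed footprint via
  the circumferential arc-length factor), so the curled cultivar
  self-occludes more — the qualitative reason the curled type is harder
  for every estimator.
- **Depth**: a nadir sensor at 78 cm; background plane at 780 mm with ±2 mm
  noise, plant pixels strictly nearer. Depth maps are written as 16-bit
  single-channel TIFF in integer millimetres (lossless round-trip,
  verified in tests); heights are cm everywhere else, with the mm→cm
  conversion in exactly one place (`structural_features()`).
- **Background and illumination**: dark, mildly textured tray with a
  lateral illumination gradient — enough structure that adaptive
  thresholding is nontrivial but solvable.

The generator emulates the *statistical* structure the estimators rely on
(size–trait allometry, growth across sessions, morphology-dependent
occlusion, green-vs-background contrast). It does not emulate specular
highlights, soil clutter, disease, wilting or camera noise, so passing
benchmarks here demonstrates correctness of the pipeline and the expected
*ordering* of methods, not field-ready accuracy on real greenhouse images.

## Preprocessing and augmentation

Images are cropped and resized with `center_crop_resize()`. Because the
capture geometry is fixed (one sensor height), the pipeline uses a
*uniform centred crop*: the plant's apparent size is the single strongest
trait signal, and per-plant bounding-box cropping (available as
`crop_box = "auto"` for irregular frames) would normalize it away.

`split_dataset()` partitions 8:2 with (cultivar, session) stratification:
per-stratum round-half-up, reconciled to the global target
`round(0.8·N)` by moving at most one sample per stratum, which reproduces
the 229/57 split of a 286-image set; 20% of the training side becomes the
validation set. Whether the original protocol stratified strictly or
merely "covered" the strata is not stated; strict stratification is the
reproducible choice.

`expand_training_set()` enlarges the training images 26-fold: the six
geometric variants (identity, three rotations, two flips) plus the four
HSV value-channel brightness factors (0.8, 0.9, 1.1, 1.2) applied to the
five non-identity geometric variants — 6 + 4·5 = 26, the unique
composition of exactly the listed transforms that yields the printed
counts (229 → 5954). The factor is always derived from the composition
rule, never hard-coded, and an alternative `"cross"` rule (6·5 = 30) is
available. Brightness follows the geometric transform; the order is
mathematically irrelevant and fixed only for byte reproducibility.
Augmentation applies to training images only — the pipeline asserts it.

## Segmentation choices

**RGB**: greenness is the a\* channel of CIE L\*a\*b\* (vegetation strongly
negative); an Otsu split within the image gives the adaptive threshold,
followed by hole filling and largest-component selection. A plausibility
check — foreground must be at least 8 a\*-units greener than background —
turns "no plant present" into an explicit error rather than a noise mask.

**Depth**: grid-seeded local k-means superpixels on (x, y, depth) with a
connectivity pass; the superpixel whose centroid is nearest the image
centre seeds the plant, then region growing merges adjacent superpixels.
The default merge criterion (`merge_rule = "floor"`) accepts superpixels
at least a margin *nearer than the estimated ground plane* (the deep tail
of the superpixel depth distribution): a sloped canopy can span far more
than any fixed seed-relative tolerance, which truncates mid-height leaves
(the strict seed-relative rule remains available as `merge_rule = "seed"`).
A depth-plausibility check flags selections that are not nearer than their
surroundings, which catches off-centre plants. GLCM texture uses 16
quantization levels over the masked min–max range (fixed gray limits are
available), displacement 1 px, ordered pairs averaged over the four
standard directions, masked pixels only; correlation of a zero-variance
channel is defined as 0 so the 92-vector is always finite.

## Benchmark sizes

Unit tests render 240-px scenes (~0.1 s each). The trait-recovery
benchmark uses 300 plants (100 per cultivar) at 360 px / 10 px·cm⁻¹,
split 240/60, and trains 40 epochs at batch 32 — sizes chosen once as the
smallest configuration at which the convolutional regressor comfortably
separates from chance and the comparison grid is stable. At these sizes
the observed test R² is ≈ 0.90–0.93 for all three traits, with the
structural linear models trailing (LR-V ≈ LR-PA > LR-H) and Area the
top-ranked handcrafted feature for every trait; the method *ordering*
(CNN above shallow baselines above LR-H) is data-dependent and therefore
logged as a warning-level expectation rather than asserted.

## Known limitations

- One plant per image; multi-plant scenes are out of scope.
- Apparent size is only meaningful at the fixed sensor height; a model
  trained at one height does not transfer to another.
- The JPEG format is not read; use PNG (RGB) and TIFF (depth).
- Depth superpixels come from a grid-seeded local k-means backend; the
  interface is pluggable, so richer superpixel objectives (entropy-rate,
  graph-based) can be swapped in. What is validated is segmentation IoU on
  synthetic scenes, not backend identity.
- `cnn_fit` checkpoints are R serializations; they are versioned but not
  portable to other frameworks.
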