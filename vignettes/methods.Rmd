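---
title: "Identifying pantry-beetle species from elytral patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying pantry-beetle species from elytral patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Food samples are routinely screened for contaminating beetles ("pantry
beetles"). When remains are found, the species must be identified, because
different species carry different regulatory consequences. Identification
relies on the pattern of the elytron — the hardened forewing — whose
surface texture of longitudinal striae, punctures and pigmentation is
species-characteristic. In practice only small elytral *fragments* are
recovered, so a useful classifier must work on fixed-size sub-images
rather than whole wings.

`elytra` implements this identification pipeline end to end:

1. **Background removal.** Specimen photographs place a dark elytron on a
   near-white field; the elytral border is detected and everything outside
   it discarded.
2. **Simulated fragmentation.** Fixed-size square tiles are sampled
   uniformly at random, strictly inside the detected border, with
   replacement — mimicking the fragments found in contaminated samples and
   multiplying the effective sample size. The study geometry is 100 tiles
   of 448 × 448 px per image.
3. **Blind (leak-free) splitting.** Whole images — never tiles — are
   split 4:1 into train and test within each species, so all tiles from
   one photograph land in exactly one partition. Without this, visually
   near-identical overlapping tiles from a single image would appear on
   both sides of the split and inflate test accuracy.
4. **Classification.** A small convolutional network with stochastic
   affine augmentation on the training stream only.
5. **Evaluation.** Tile-level confusion matrix and per-species
   one-vs-rest metrics: precision, recall (sensitivity), specificity, and
   the Matthews correlation coefficient, plus the macro average of
   per-species accuracies.

Because real specimen collections are not redistributable, the package
carries a procedural generator of synthetic elytra images with exact
ground-truth masks; every stage is tested against it.

## The classifier

The network is deliberately small:

```
input S×S×3
4 × [ conv 3×3, ReLU  →  max-pool 2×2 ]
flatten → dense 128, ReLU → dropout → dense K, softmax
```

trained with categorical cross-entropy and the Adam optimizer
(learning rate 10⁻³, β₁ = 0.9, β₂ = 0.999), batch size 32. Convolutions
use "same" zero padding, so an input side divisible by 16 passes the four
pooling stages evenly (448 → 224 → 112 → 56 → 28). The 128-unit
penultimate layer doubles as a feature extractor
(`extract_features()`), and those features can be projected to 2-D for
inspection (`embed_2d()`).

Choices the architecture description leaves open were fixed once:

* **Filter counts** default to (32, 64, 128, 256) — the standard doubling
  schedule feeding a 128-unit dense head. Desk-scale experiments in the
  tests use smaller counts; the shape contract (4 blocks, 3×3 kernels,
  2×2 pools, dense 128) never changes.
* **Dropout** defaults to rate 0.5, placed between the 128-unit layer and
  the output — the canonical placement for dense-layer dropout.
* **Pixel scaling**: 8-bit inputs are rescaled by 1/255 so the network
  always sees `[0, 1]`.

There is no deep-learning framework behind these functions: convolution,
pooling, backpropagation and Adam are implemented in vectorized R (an
im2col unrolling turns each convolution into one BLAS matrix product).
Correctness is established by a finite-difference gradient check in the
test suite — every analytic gradient is compared against a numerical
derivative on a tiny network — rather than by appeal to a framework.
Training is single-threaded-deterministic: all shuffling, augmentation
draws and dropout masks flow from one seed, so identical seeds and data
reproduce identical histories.

## Augmentation policy

Training tiles (and only training tiles — the fitted model's `$audit`
table records per-stream counts) pass through one affine resampling
composed of rotation, shear along x, isotropic zoom, then translation,
about the tile center, followed by an optional exact horizontal mirror.
Out-of-image samples are filled with the nearest edge pixel; interpolation
is bilinear and happens in a single pass. Defaults:

| parameter          | default | meaning                                  |
|--------------------|---------|------------------------------------------|
| rotation_range     | 40      | |angle| ≤ 40°, uniform                   |
| width/height shift | 0.2     | |shift| ≤ 20% of the side, uniform       |
| shear_range        | 0.2     | |shear| ≤ 0.2° (counterclockwise)        |
| zoom_range         | 0.2     | scale ∈ [0.8, 1.2], uniform, both axes   |
| horizontal_flip    | on      | probability 0.5                          |
| fill_mode          | nearest | edge-pixel fill                          |

A zero-range configuration is a bit-exact identity, asserted in the
tests. (Narrative descriptions of this policy sometimes quote slightly
different numbers — 30° rotation, 15% zoom, 10% shear; the tabulated
values above are taken as authoritative, and the discrepancy is simply
documented here rather than resolved.)

## Border detection

The elytral border is "the line of maximum change in contrast" between
the dark wing and the white field. The realization here:

1. Grayscale, Gaussian smoothing (σ = 2 px). Pixels above 0.92 are
   candidate background; the largest complementary connected component is
   kept and its holes filled. An image with *no* pixel at or below the
   threshold raises a no-foreground error; a uniformly dark image yields a
   full-frame mask.
2. The boundary is then snapped toward the maximum-gradient locus: for a
   smoothed step edge, the gradient peaks where intensity crosses the
   midpoint between the two plateaus, so the mask is re-thresholded at
   (mean foreground + mean background)/2.
3. The refinement is confined to a ±3 px band (morphological
   dilation/erosion with a disc of radius 3) around the initial boundary,
   so it can sharpen but never relocate the border.

Against the generator's exact truth masks this attains median IoU ≈ 0.99;
the tests require ≥ 0.95 over 20 images.

Tile containment is exact, not approximate: a summed-area table of the
mask verifies that every candidate `size × size` footprint covers exactly
`size²` mask-true pixels. Sampling is uniform over all valid top-left
positions, with replacement — the number of crops is fixed (default 100)
regardless of elytron area, so overlapping and duplicate tiles are
possible and permitted. Coordinates are 1-based, row-major, inclusive,
with the origin at the top-left — the R convention; the containment
arithmetic is stated and tested in those terms.

## Split arithmetic

Per species, `|test| = round(test_fraction × n)`, clamped to
`[1, n − 1]`. At the study geometry — 27 species × 20 images, fraction
0.2, 100 tiles per image — this gives exactly 16 train and 4 test images
per species: 43,200 training and 10,800 test tiles. (A published figure
of 46,300 training tiles is arithmetically inconsistent with those stated
parameters, suggesting unequal image counts per species in the original
collection; the package supports unequal counts and always reports exact
conservation: train + test + excluded × n = images × n.) The clamp to a
non-empty train partition is this package's own safeguard beyond the
minimum-one-test-image rule.

A repeated-splits mode (independent split seeds) is available through the
pipeline configuration for estimating split-to-split variability; the
default, matching common practice, is a single split with per-epoch
validation.

## The synthetic generator

The generator is a first-class module, not a test shim. Each synthetic
species is a parameter set: base gray level, stria period and
orientation, spot density and radius, and a texture seed. Rendering
composes:

* an elongated convex footprint — an axis-aligned superellipse (exponent
  2.5, semi-axes 0.42 W × 0.36 H) with a mild random two-harmonic
  boundary perturbation (≤ 2%), giving simple containment math and an
  elytron-like silhouette;
* sinusoidal striae (amplitude 0.12) oriented per species, with a
  species-fixed phase so individuals share pattern alignment;
* Poisson-scattered darker soft discs (the punctures);
* low-amplitude smooth value noise (bilinear interpolation of a coarse
  uniform grid with smoothstep easing);
* a near-white background (0.97 ± small smooth variation).

Parameters for a set of species are drawn on jittered evenly-spaced grids
(base intensity over [0.18, 0.72], orientation over [0°, 180°)) so any
requested number of species is pairwise distinct and learnable; a
`separation` dial collapses the grid toward a single texture family for
chance-level controls.

Three variation modes emulate the intraspecies effects seen in real
collections:

* **maturity_darkening** `m`: foreground becomes
  `base·(1 − 0.45 m) + pattern·(1 + 0.6 m)` — darker overall with more
  prominent pattern, as in older beetles;
* **variegation** `v`: pattern amplitude is multiplied by a smooth
  low-frequency field spanning `[1 − v, 1 + v]`, so regions of one
  elytron differ in pattern prominence;
* **background_fiber** `f`: oriented random line segments (a filter-paper
  texture) are composited over the background only, with opacity `f`.

The zero profile is exactly the base texture. All randomness flows
through one seeded generator per call; identical arguments give identical
pixels, and identical generation seeds give byte-identical PNGs on disk.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: photo-realistic cuticle rendering, setae,
specular glare, frontal-side damage, sex or individual variation beyond
the three modes above, and the actual texture statistics of any real
species (no quantitative description of those statistics is available to
calibrate against). Synthetic results demonstrate that the pipeline's
machinery is correct and that its qualitative properties hold — not that
any particular real-data accuracy would be reproduced.

## Evaluation conventions

* Argmax ties break toward the lowest class index (deterministic).
* "Species-wise accuracy" is per-class recall — the diagonal of the
  row-percent confusion matrix — and the macro average of those recalls is
  the "average prediction accuracy".
* Any metric with a zero denominator (including the MCC's product
  denominator) is defined as 0; a constant predictor therefore scores
  MCC 0 for every class.
* All metric arithmetic starts from exact integer counts; the test suite
  checks every metric against a brute-force implementation that counts
  raw label/prediction pairs directly.
* Metrics are tile-level by default, matching evaluation on sub-images;
  `majority_vote()` offers optional image-level aggregation but no
  pipeline enables it by default.
* The 2-D feature embedding is a principal-component projection: linear,
  deterministic, duplicate-preserving. It is a plotting aid, not part of
  the classification path.

## Desk-scale study conditions

The test suite and the acceptance script exercise the pipeline at sizes
chosen to be comfortably reproducible on one CPU, as the package's own
standard conditions:

* count arithmetic at the full study geometry (27 × 20 images — no pixels
  rendered);
* border detection on 20 images of 144 × 192 px;
* learnability: 3 well-separated species × 6 images of 160 × 224 px,
  20 tiles of 64 px per image, filters (8, 16, 32, 64), 10 epochs with
  augmentation — reaching ≥ 90% tile-level test accuracy;
* chance control: two labels over one shared texture, 10 images each,
  judged against an image-level binomial band (8 held-out images,
  p = 0.5, central 99% interval), since tiles within an image are
  correlated and do not contribute independent Bernoulli trials;
* degradation: mean test accuracy across 5 seeds with maturity spread 0
  versus 1 across each species' images; the spread-1 mean must not exceed
  the spread-0 mean by more than 0.05 (tolerance fixed before running, to
  absorb seed noise in a 5-seed mean).

## Known limitations

* The CNN runs on the CPU in R; it is sized for desk-scale experiments
  and method validation, not for training on tens of thousands of
  448-px tiles.
* Border detection assumes a near-white background; dark or cluttered
  backgrounds are out of scope, as is glare removal (the imaging protocol
  this pipeline targets already eliminates glare).
* The max-pool gradient routes ties to all maximal positions; with
  continuous activations ties have measure zero.
* `round()` uses R's banker's rounding at exact .5 fractions of
  `test_fraction × n`; the clamp to `[1, n − 1]` is unaffected.
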