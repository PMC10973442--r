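---
title: "Methods: texture features and dynamic-learning classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture features and dynamic-learning classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcicm)
```

## The problem and the model

Histopathology image collections are large and labeling them requires
expert time. `bcicm` addresses the two-class case (benign vs. malignant
tissue) without labels: images are reduced to a small texture descriptor,
and the descriptors are partitioned by an unsupervised optimizer that
searches directly for a good *pair* of cluster centers. The pipeline's
working assumption is that the two tissue classes differ in texture
statistics — malignant tissue tends toward rougher, higher-contrast, less
locally homogeneous texture — so that a 4-dimensional gray-level
co-occurrence summary separates them in Euclidean space.

### Texture descriptor

For an M×N image with `N_g` gray levels, the co-occurrence matrix
`P(i, j; d, θ)` counts ordered pixel pairs at displacement `d` in direction
`θ` whose gray levels are `(i, j)`. On the normalized matrix `p` the package
computes energy (ASM), contrast (CON), inverse difference moment (IDM) and
correlation (COR); entropy (bits) and Tamura coarseness are optional extras
kept out of the core vector because the four chosen statistics are
low-redundancy and cheap. All four statistics are computed on the
*normalized* table, making them invariant to image size; correlation is
additionally normalized by the marginal standard deviations so it lies in
[−1, 1].

### Clustering by dynamic learning

A particle encodes `(c₁, c₂)` as one 2D-dimensional vector, scored by the
sum of nearest-center distances. The population improves by a Gaussian
pairwise-learning rule: the worse particle of a random pair samples each
coordinate from `N((pᵢ+pⱼ)/2, |pᵢ−pⱼ|)`, the better one from
`N((pⱼ+g)/2, |pⱼ−g|)` with `g` the global best. Spreads shrink as the
population agrees, so the search contracts from exploration to refinement
without a schedule. Note the objective is a sum of *distances*, not squared
distances: the optimum centers are coordinate-wise medians of their
clusters, which is slightly more outlier-robust than k-means means; on
well-separated data both coincide for practical purposes (the test suite
checks the converged objective against Lloyd's k-means as an independent
reference).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `resolution` | 40 | px | Smallest protocol size; texture statistics stabilize already at 40 px and extraction is fastest there. 100/200/400 supported via `resolution_sweep()`. |
| `n_levels` (N_g) | 8 | levels | Keeps the 8×8 GLCM dense even for 40×40 images (1560 symmetric pairs per angle fill 64 cells); larger N_g mostly adds sampling noise at this size. |
| `distance` (d) | 1 | px | Adjacent-pixel co-occurrence, the standard fine-texture choice. |
| `angles` (θ) | 0/45/90/135 | deg | All four canonical directions, averaged (normalized per angle) with symmetric counting: one rotation-tolerant value per image, the standard Haralick practice when one value per image is reported. |
| `feature_scaling` | minmax | — | CON is unbounded (up to (N_g−1)²) while ASM/IDM live in (0,1]; without per-feature scaling, contrast would dominate the Euclidean geometry. `none` and `zscore` are available. |
| `pop_size` | 30 | particles | Converges on every shipped fixture in well under a second; doubling it has shown no benefit on 4-D descriptors. |
| `max_iter` | 200 | iterations | Comfortably past the observed convergence knee (≈50 iterations on the blob fixture). |
| `split_fraction` | 0.8 | — | The 80/20 stratified split used by the supervised baselines only; the unsupervised pipeline clusters all presented samples, since it consumes no labels and needs no held-out set. |

## Numerical choices and degenerate inputs

* **Quantization** bins `[0, 255]` (or `[0, 1]`) uniformly and is monotone;
  a 0..255 ramp at 4 levels yields exactly 64 pixels per level.
* **Constant images** have undefined correlation (zero marginal variance).
  `glcm_cor()` raises a typed error; `extract_features()` substitutes 0 with
  a warning so a single degenerate image cannot abort a batch run.
* **Acceptance rule**: a candidate replaces a particle's personal best only
  on *strict* improvement, and the global best is refreshed after every
  evaluation. This makes the global-best history non-increasing by
  construction — a property the tests assert across 50 seeds.
* **Particle state** is identified with the personal best (the learning
  rule reads only personal bests and the global best), the simplest scheme
  consistent with recording historical optima for subsequent calculation.
* **Neighbor topology**: a uniformly random distinct particle per
  iteration; with `pop_size = 1` the particle pairs with itself and the
  update degenerates to a no-op rather than crashing.
* **Tie-breaks**: equal objectives in a pair leave the first-selected
  particle in the "worse" role; equidistant points go to cluster 0; an
  alignment tie keeps the identity mapping (cluster 0 = benign); Tamura's
  per-pixel best window prefers the smallest exponent, so a constant image
  has coarseness exactly 1.
* **No clamping**: the Gaussian draw is not projected back into the
  initialization bounds — the learning rule has no projection step, and the
  contracting spreads keep iterates near the data.
* **Sensitivity denominator**: SEN = TP/(TP+FN), the standard definition —
  the denominator is the number of true positives plus missed positives,
  never a quantity involving TN (a substitution occasionally seen in
  transcribed formula collections, and inconsistent with the tabulated
  values the tests reproduce).
* **Hard-classifier AUC**: a single-operating-point classifier has the
  two-segment ROC with trapezoidal area (SEN+SPE)/2; `metrics_report()`
  reports that value, and the continuous margin-score ROC is emitted as a
  separate artifact.

## What the synthetic generator does and does not emulate

`make_texture_dataset()` produces Gaussian noise fields smoothed with a
separable truncated-Gaussian kernel (reflected edges): the "benign" class
with blur σ = 8 px (fine, homogeneous texture — high IDM, low CON), the
"malignant" class unsmoothed (rough — high CON). After smoothing, each
field is re-standardized to mean 128 / sd 40 before 8-bit clipping so that
coarseness and contrast are controlled independently and the smooth class
does not degenerate to a constant image. Blurred noise was chosen over
checkerboards because it yields graded, realistic GLCM statistics at
40–400 px. Defaults are 50 images per class at 40 px, written as
deterministic 8-bit grayscale PNGs with the generator settings recorded
alongside (`generator.json`).

This fixture validates the *mechanics* — feature separability, clustering,
alignment, metrics — not clinical performance. It has no H&E stain
appearance, no nuclear morphology, no staining or compression artifacts,
and its two classes are far better separated than real benign/malignant
texture distributions; passing on it says nothing quantitative about
accuracy on real biopsy collections.

`make_feature_blobs()` skips the image stage entirely: two isotropic
Gaussian clouds (default 100 points/class, 4-D, centers 10 sd apart) with
the ground-truth centers returned for recovery assertions.

## Problem sizes used by the shipped tests

The test suite runs the full study conditions: co-occurrence counting is
checked against a brute-force pair counter over every image size up to 6×6
(N_g ≤ 4, all four angles, directional and symmetric); feature ranges over
1000 random images; optimizer monotonicity over 50 seeds; center recovery
(within 0.5 sd, objective within 1.05× of converged Lloyd's k-means) over a
10-seed panel on the default blob fixture; and the end-to-end pipeline on
the default 50-per-class texture fixture, where it must reach ≥ 95%
accuracy and ≥ 90% AUC and produce byte-identical artifacts across repeated
seeded runs. The whole suite completes in about half a minute on one CPU.

## Known limitations

* Strictly two classes; the eight benign/malignant subtypes of public
  collections are ingested as metadata only.
* The texture descriptor is global per image: spatially heterogeneous
  slides (tumor region plus large background) dilute the signal, and no
  tiling/aggregation stage is provided.
* The optimizer is stochastic; while every shipped fixture converges on
  every tested seed, a pathological seed on hard data can stop short of the
  global optimum — run a few seeds and keep the best objective when that
  matters.
* Baselines use library-default hyperparameters (recorded in the result)
  rather than tuned ones; they are a sanity corridor, not a benchmark.
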