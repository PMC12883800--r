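---
title: "Sub-compartment vegetation cover change detection: models and methods"
author: "fscchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-compartment vegetation cover change detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Forest inventories are organized around forest sub-compartments (FSCs):
polygons of 100 m² up to tens of hectares that are internally homogeneous in
vegetation cover type. Five types are distinguished here — Arbor, Shrub,
Bamboo, Bare and Other — and the monitoring question is which FSCs changed
type between two image epochs. The pipeline classifies each epoch
independently from 10 m multispectral imagery and compares labels per FSC
(post-classification comparison). This keeps the analysis aligned with the
management unit, avoids pixel-level change noise, and produces outputs
(transition matrices, change polygons) that slot directly into inventory
updating.

## Patch model and its assumptions

Each FSC contributes a single 5×5-pixel window centered on the pixel nearest
an interior anchor point. The anchor is the geometric centroid when that lies
inside the polygon; for concave polygons whose centroid falls outside, a
guaranteed-interior representative point is used instead (midpoint of the
widest span on a horizontal scanline), because the property that matters is
that the window samples the unit's own pixels, not its neighbors'. Map
coordinates go to pixel indices by inverse affine transform with
round-half-down tie-breaking (0-based row/col, pixel-center registration),
fixed so patch windows are bit-reproducible.

Assumptions and consequences:

* For FSCs above 3,000 m² the window is, with high probability, fully
  interior (verified as a property test at ≥95% for units above 1 ha).
  Units at or below 3,000 m² (strictly `area > 3000` is required for
  training) are predicted anyway but flagged `in_distribution = FALSE`;
  their windows mix neighboring units and their accuracy is reported
  separately. This mirrors the operational choice of excluding small noisy
  units from training while still screening them.
* Windows touching nodata (cloud-masked) pixels are excluded, not imputed —
  imputation would fabricate texture.

## Features

Spectral: per-window means of B2, B3, B4, B8 (plus B11/B12 when present) and
ten band-ratio indices (NDVI, EVI, NBRI, SAVI with L = 0.5 and the 1.5
scaling, RVI, DVI, NDBI, BGRVI, GNDVI, NDWI). Indices are evaluated on window
band means rather than per pixel; the two differ for ratio indices, the
band-mean form is cheaper and deterministic, and a `viPerPixel` switch is
provided. Note that NDWI = −GNDVI identically; both are kept so either
convention is available downstream, and gain-based selection discards the
redundancy on its own. A denominator below 1e-12 returns 0 with a degenerate
flag rather than an infinity.

Texture: gray-level co-occurrence matrices on the NIR band (B8) by default —
the band with the strongest class signal — quantized to N = 32 levels
between the window minimum and maximum with right-closed bins (a constant
window maps to level 0), offset distance 1, accumulated over the symmetric
4-angle set and normalized. Eight metrics are derived: MEAN, VAR, HOM, CON,
DIS, ENT (bits, with 0·log 0 = 0), ENE, COR. VAR is the GLCM variance
Σ(i−μ)²P(i,j) around the GLCM mean, and DIS is Σ|i−j|P(i,j); these are the
standard forms — published variants of these two formulas are sometimes
typographically corrupted (a sample-variance-style VAR and an extra i factor
in DIS) in ways that contradict their own verbal definitions, so the package
implements the standard definitions and cross-checks all eight metrics
against a brute-force pair-enumeration oracle in the tests. When a marginal
standard deviation is zero, COR is reported as 0 with a degenerate flag.
Quantization depth, distance, angles and source bands are config-exposed
since no single convention is universal.

## Grouped feature selection

Spectral features (bands + indices) and texture features are ranked in two
independent groups, so the larger spectral group cannot crowd out texture.
Within each group a gradient-boosted multiclass model (100 rounds, depth 4,
learning rate 0.1, single-threaded and seeded for determinism) attributes
gain to each feature; gains are normalized to sum 1 per group and the
smallest prefix reaching a cumulative contribution threshold (default 0.85
per group) is selected. Constant or never-used features receive zero gain
and rank last. Selection is monotone in the threshold.

## Classifiers

All models standardize features with training-set means/SDs and share a fixed
class order (Arbor, Shrub, Bamboo, Bare, Other) used for probability columns
and argmax tie-breaking (ties go to the earlier class).

* **RF**: 50 trees, maximum depth 8, seeded (default 42).
* **SVM**: RBF kernel, C = 100, adaptive gamma 1/(d · var(X)) on the
  standardized features, probability outputs.
* **BPNN**: input → two ReLU hidden layers (default 50/50) → softmax;
  cross-entropy loss minimized by full-batch Adam (default learning rate
  0.01, chosen as the geometric middle of the 0.001–0.1 exploration range);
  300 epochs; per-epoch loss recorded; deterministic under the seed.
  Non-finite loss aborts with diagnostics.
* **PSO-BPNN**: canonical inertia-weight particle swarm
  (v ← w·v + c1·r1·(pbest−x) + c2·r2·(gbest−x), per-dimension uniform r1,
  r2) with w decayed linearly 0.9 → 0.4, c1 = c2 = 1.5, velocities clamped
  to 20% of each dimension's range, positions clipped to bounds, non-finite
  fitness penalized with +∞. Two stages, because a joint encoding of
  architecture and weights has variable dimensionality:
  1. search (hidden1, hidden2, learning rate) in (16–128, 16–128,
     0.001–0.1), hidden sizes rounded to integers; fitness is the
     validation cross-entropy after a short proxy training (default 30
     epochs here; tests and the acceptance script use 25) on an internal
     stratified 80/20 split;
  2. search the initial weight vector of the stage-1 architecture in
     ±0.5 per dimension, with one particle seeded at the standard He
     initialization so the stage can only improve on it; stage 2 can be
     disabled.
  The final network trains in full (Adam, 300 epochs) from the stage-2
  initialization.

### What the hybrid does and does not buy

On the synthetic scenes the hybrid's tuned learning rate and optimized
initialization reliably reach a lower final training loss than the fixed
50/50 network (compared as paired-seed medians in the tests), i.e. it
converges faster and further. Holdout *accuracy*, however, saturates on this
task for both models (≈0.92–0.98), so per-seed accuracy differences are
sampling noise at holdout sizes of ~100–250 units; the tests therefore assert
accuracy non-inferiority (paired medians within 0.02) rather than a win rate.
With desk-scale swarm budgets (8–10 particles × 6–8 iterations instead of
50 × 100), the stage-1 fitness is also noisy enough that an occasional run
picks an aggressive learning rate whose late-stage instability a 25-epoch
proxy cannot see — a limitation of the shortened proxy, not of the method.

## Change detection and evaluation

Per-FSC labels from the two epochs give change records
(`changed ⇔ from ≠ to`); units unclassified in either epoch (nodata windows)
are excluded from the transition matrix and counted separately. Transition
matrices put the earlier epoch in rows — the orientation is fixed by the
bundled county-scale table whose row sums match the published class totals
exactly (the companion one-year-later block of that table is not internally
consistent under either orientation with its quoted percentages, e.g. the
8.53% bamboo-to-arbor figure; the package keeps the verifiable convention).
Retention rate is the diagonal share of a row; conversion rates are
off-diagonal shares; both are left unrounded until presentation.

Accuracy metrics come from the reference-by-predicted confusion matrix:
OA = trace/total; per-class one-vs-rest precision, recall and F1 with
unweighted macro averages by default (the binary-form definitions are applied
per class because a 5-class task reports single summary values; weighted
averaging is available); kappa = (Po − Pe)/(1 − Pe) with Pe from the product
of marginals. A class never predicted gets precision 0 with a flag rather
than NaN.

Change-detection accounting intersects reference changed-unit ids with
detected ids: detected + missed = |reference| always. The changed-only
detection rate is reported rather than a binary OA over all units, because
the latter's denominator convention is ambiguous in published accounts (the
bundled validation counts give 273/329 = 82.98%, while 82.7% is quoted
elsewhere for the same numbers).

Spatial clustering of change locations uses the Clark–Evans nearest neighbor
index on change-polygon centroids: NNI = observed mean NN distance /
(0.5·√(area/n)), SE = 0.26136/√(n²/area), two-sided normal p, no edge
correction — the convention of the common GIS implementations. NNI < 1
indicates clustering; a square lattice gives exactly 2.0, which the tests use
as a closed-form check.

## The synthetic scene generator

`generateScenePair()` provides ground-truthed inputs since real inventory
data are not distributable. Design:

* **Tessellation**: Voronoi cells of a seeded point process on a 460×460
  grid of 10 m pixels (2,200 units by default). The process mixes 85%
  uniform seeds with 15% clustered seeds (per-cluster Gaussian spread drawn
  log-uniformly from 1.2 px to 5% of the grid extent), plus two deterministic
  constructs: a seed with a guaranteed exclusion disc (one cell ≥ ~10% of the
  grid) and a 5-seed sliver construct (one cell of about one pixel), so cell
  areas span the full realistic range (~100 m² to very large) while most
  units stay above the 3,000 m² training threshold — the defaults yield
  roughly 1,000 training-eligible units after the 80/20 split.
* **Class proportions** default to a rebalanced training-style composition
  (0.4387/0.4002/0.1397/0.0073/0.0141) rather than the extreme dominance of
  one class in a full inventory, so every class is learnable.
* **Signatures**: each class has band means (vegetated classes with NIR well
  above red; Bare with red ≥ NIR), a noise multiplier, and a texture
  correlation length. Arbor (2.5 px) and Bamboo (0.6 px) are spectrally close
  but texturally distinct — by design, so texture features carry real
  information and the feature-ablation ordering (bands ≤ bands+VIs ≤
  bands+VIs+texture) reflects genuine signal, not an artifact.
* **Rendering**: pixel value = class band mean + noiseSd × smoothed
  standardized Gaussian field (separable Gaussian kernel at the class's
  correlation length), per band, class and epoch. noiseSd defaults to 0.04
  reflectance — enough overlap that classification is non-trivial but
  recoverable.
* **Changes**: exactly `round(changeFraction × n)` units, drawn uniformly
  among units above 3,000 m² (so injected changes are learnable), relabeled
  uniformly among the other four classes. Identical seeds give bit-identical
  scenes.

What the generator does **not** emulate: atmospheric and radiometric
artifacts, topographic illumination, phenology, mixed pixels inside a unit,
spatially structured (non-uniform) change processes, and real class-boundary
geometry. Passing tests on these scenes therefore demonstrate that the
pipeline recovers structure it assumes — separable signatures and clean
labels — not field performance on real imagery.

## Problem sizes used in tests and the acceptance script

The acceptance run trains PSO-BPNN on the full default scene (~1,000
training units) with swarm 10 × 8 iterations per stage and a 25-epoch proxy,
and measures the feature ablation on ten 280×280/800-unit scenes with the
plain BPNN (300 epochs). These sizes are the package's chosen benchmark
configuration; larger swarms only sharpen the stage-1 choices.

## Numerical conventions

* Quantization: right-closed uniform bins; values exactly on an interior
  edge bin low; constant windows map to level 0.
* GLCM: symmetric accumulation (each pair counted in both directions), then
  normalization; entropy in bits.
* Probability ties at prediction: earlier class in the fixed class order.
* Standardization: zero-variance features get scale 1 (they contribute 0
  after centering).
* Random draws: every stochastic step (tessellation, noise, splits, PSO,
  network init, boosting) consumes a named integer seed; reruns are
  bit-identical.
* Stage artifacts carry a manifest with a hash of the config sections the
  stage depends on; downstream stages refuse stale upstream artifacts.

## Known limitations

* Raster I/O uses the package's own TIFF + JSON-sidecar container (written
  and read by `writeScene()`/`readScene()`); standard GeoTIFF tags are
  neither read nor written, and vector input is GeoJSON only.
* Affine transforms are restricted to axis-aligned, north-up grids.
* Self-intersecting polygons are rejected with a report (no repair).
* The NNI has no edge correction; for small n in elongated regions it is
  biased upward.
* B11/B12 are consumed at the raster's resolution as provided; no internal
  resampling is performed.
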