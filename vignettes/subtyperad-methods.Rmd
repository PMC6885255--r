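---
title: "Methods: segmentation, radiomics and multi-model feature elimination in subtyperad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, radiomics and multi-model feature elimination in subtyperad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

subtyperad implements a radiomics pipeline for multi-phase dynamic
contrast-enhanced MRI (DCE-MRI) of breast lesions: lesion segmentation by
seeded region growing with a dynamically determined threshold, a fixed
146-value feature suite over three phases, multi-model recursive feature
elimination (mmRFE), and multi-class molecular-subtype classification
(luminal A, luminal B, HER-2 over-expressing, basal-like) under class
imbalance. This vignette is the package's account of the underlying
methods, the choices that were genuinely open, and what the synthetic
validation does and does not establish.

## Segmentation

A radiologist-style annotation is a loose rectangle (ROI) around the
lesion. The seed is the geometric center of the ROI; the growth threshold
`t*` is computed from the 256-bin histogram of the ROI patch by Otsu's
method (maximizing between-class variance; ties resolve to the smallest
level, and the foreground is `I > t*`). The lesion mask is the 8-connected
component of the thresholded foreground that contains the seed. Two points
were genuinely open and are resolved as follows:

* **Growth criterion.** "Connected Otsu-foreground component containing
  the seed" is the default because it is parameter-free and deterministic.
  An alternative reading — accept a neighbor `p` when
  `|I(p) - I(seed)| < |I(seed) - t*|` — is available via
  `grow_options(criterion = "seed_delta")`.
* **Threshold domain.** Otsu is applied to the ROI patch, not the whole
  image: the lesion/background two-class structure only exists locally.

The classical fixed-threshold baseline grows from the same seed and
accepts a neighbor when `|I(p) - I(seed)| < T`. Its failure modes motivate
the dynamic mode: a single `T` undersegments heterogeneous lesions and
cannot adapt when lesion/background contrast varies across cases. If the
ROI center happens to fall below `t*` (possible for concave lesions), the
seed is relocated to the brightest pixel in a 7×7 window around the
center. Segmentation quality is scored by the dice coefficient
`S = 2|X∩Y| / (|X|+|Y|)`. Segmentation defaults to the first post-contrast
phase, where lesions are enhanced; this is configurable.

## The feature suite

146 labeled values per lesion, in five blocks (`feature_schema()` gives
the canonical order):

* **GLCM texture (F1–F15).** Lesion intensities are min–max quantized to
  16 gray levels (the paper-standard 8–32 range; configurable), and
  co-occurrences at distance 1 are accumulated symmetrically over the four
  directions 0°, 45°, 90°, 135°, counting only pairs with both pixels in
  the mask. Energy, contrast, correlation, entropy and the homogeneity
  statistic Σ p/(1+(i−j)²) — called the *deficit matrix* in the clinical
  literature this package follows — are averaged over the four directions,
  giving 5 values per phase. Correlation is 0 by convention when a
  marginal variance vanishes.
* **LBP texture (F16\_b, F17\_b, F18\_b).** The 8-bit local binary
  pattern code `Σ S(g_p − g_c)·2^p` with `S(u) = 1` for `u ≥ 0`, neighbor
  p = 0 at the top-left and p increasing clockwise. Codes are computed for
  every mask pixel whose 3×3 neighborhood fits in the image; neighbors are
  read from the raw image even when they fall outside the mask (masking
  them out would distort codes along the boundary, which is where the
  texture signal lives). The 256-bin histogram is normalized by the number
  of coded pixels, and the 31 bins {1–15, 240–255} are retained per phase
  — the low and high codes that capture near-uniform and strong-gradient
  neighborhoods.
* **Kinetics (T1–T13).** Pixel-wise enhancement
  `R = (I_T − I_t)/I_t` between phase pairs (1,0), (2,0), (2,1) yields
  std/mean/max per pair (population standard deviations throughout;
  pixels with `I_t = 0` are excluded as a division guard). Whole-lesion
  enhancement rates `ER_i0 = S_i/S_0` and absorption rates
  `AR_i0 = (S_i − S_0)/S_0 × 100%` fill T10–T13; AR is computed as
  `(ER − 1)·100` so the algebraic identity between the two holds to the
  last bit.
* **Statistics (C1–C18).** Per phase: mean, population standard
  deviation, Shannon entropy of the 256-bin grayscale histogram (base-2
  logs, 0·log 0 ≡ 0), maximum, bias (skewness) and peak (excess
  kurtosis); bias and peak are 0 by convention for constant regions.
* **Morphology (M1–M7).** Boundary pixels (mask pixels with a 4-neighbor
  outside) are ordered by polar angle about the centroid; radial lengths
  normalized by their maximum give the NRL sequence. M1/M2 are its
  mean/SD, M4 roughness is the cyclic mean absolute difference of
  consecutive NRL values, M5 smoothness the cyclic mean deviation from the
  two-neighbor average. The perimeter is the Moore-traced contour length
  with weight 1 per axial and √2 per diagonal step; M3 compactness is
  P²/(4πA), M6 roundness its reciprocal, M7 the pixel count.

Label orders within the kinetic and statistics blocks follow the schema
comment in `R/features-extract.R`; the full table emits all 146 labels and
`drop_invalid_columns()` removes features that are zero in every case,
logging what it removed (so the effective feature count per run is always
documented — on real cohorts many of the retained LBP bins are never
observed and drop out here).

## Feature selection

Traditional RFE fits one model, ranks features by importance, removes the
least important, and repeats. Different models keep different subsets,
which is precisely the instability mmRFE addresses: at each iteration
*every* model ranks the surviving features, the 0-based rank positions are
summed into a composite score, each model's cross-validated accuracy on
the surviving set is recorded, and the composite-worst features are
removed. Importance is the mean absolute standardized coefficient for the
linear models (multinomial logistic regression; linear SVM via
one-vs-rest weight vectors) and impurity/gain importance for the tree
ensembles. Ties keep table column order. The selected subset is the
recorded iteration where every model reaches the accuracy threshold θ
(default 0.8) and the minimum per-model accuracy is maximal; ties resolve
to the higher mean accuracy, then the smaller subset. When no iteration
reaches θ the result is an explicit empty selection with the best
available subset alongside, not an exception.

Open choices, resolved: elimination step defaults to 1 feature per
iteration (a fraction of the surviving set may be configured — useful at
146 features, where `step = 0.1` cuts runtime tenfold with no measurable
effect on the selected subset); importance is fitted on the full table per
iteration while accuracy comes from stratified 5-fold CV (leave-one-out is
available as the fidelity mode, k-fold as the fast default); features are
z-scored inside each CV fold for the linear models only.

## Classification and evaluation

Defaults: LR with L2 decay 1; linear SVM, cost 1, probability estimates;
RF with 500 trees; GBDT with 300 rounds, learning rate 0.1, depth 3. All
are exposed in `model_config()`. Out-of-fold predictions are pooled into
one confusion matrix, from which accuracy and per-class
precision/recall/F1 are computed; headline averages are macro
(unweighted), with weighted averages also emitted. No resampling or class
weighting is applied by default — the design addresses imbalance through
feature robustness, not reweighting — but per-class metrics make the
imbalance behavior visible. The ensemble is a per-sample majority vote
over the four fitted models; vote ties break toward the highest mean
predicted class probability, residual ties by the fixed order GBDT, SVM,
RF, LR (an interpretation: the combination rule was an open choice, and
majority voting is this package's definition).

## The phantom generator

Real DCE-MRI cohorts with subtype labels are not freely available, so the
package ships a phantom generator whose cases exercise every pipeline
stage with known ground truth:

* **Shape:** star-convex boundary `r(θ) = r0(1 + Σ a_j cos(jθ + φ_j))`
  with random phases; the irregularity amplitude fixes Σ a_j, so roughness
  and NRL spread grow monotonically with it.
* **Intensity:** background level 30, lesion baseline 70 (8-bit scale),
  class-dependent smooth intra-lesion texture fields (Gaussian-smoothed
  white noise, SD 6–18, correlation length 3–5 px), additive Gaussian
  noise SD 4 everywhere, intensities rounded and clipped to [0, 255] so
  that the 256-bin histogram operators are well defined.
* **Kinetics:** per-pixel enhancement ratios drawn around class targets
  (ratio1 1.6/2.0/2.4/2.8 and ratio2 1.9/2.3/2.1/2.2 for classes A–D,
  with relative heterogeneity 0.10–0.18) — class A emulates slow
  persistent enhancement and class D fast wash-in with partial washout.
* **Cohort:** class counts by largest-remainder rounding of the
  183/241/143/70 imbalance (exact at n = 637); three phases by default
  (the clinical acquisition continues to eight, but the feature suite uses
  T0–T2; the count is configurable); ROI boxes pad the truth bounding box
  by 4 px, mimicking a loose manual rectangle.

The class profiles are stand-ins: nothing ties a given texture SD or
enhancement ratio to an actual molecular subtype, so passing tests show
that the pipeline recovers *planted* structure, not that it would reach
any particular accuracy on patients. The phantoms also omit bias fields,
motion, partial-volume effects and background parenchymal enhancement, so
real-data segmentation is harder than the benchmark suggests. Cases are
2D single slices throughout (features are defined on 2D ROIs).

## Validation design and problem sizes

All tests run on data generated in-process. The scales were chosen so the
full suite completes in a couple of minutes while keeping every check
statistically meaningful:

* Texture/kinetics/statistics extractors are compared to brute-force
  enumeration oracles on 20 random lesions up to 10×10; the Otsu
  threshold to exhaustive variance search on 100 random patches.
* The segmentation benchmark draws 50 cases with per-case lesion/background
  contrast uniform in [60, 180] and noise SD 4; the dynamic mode's mean
  dice must reach 0.90 and at least match the best fixed threshold in
  {20, 30, 40, 50}.
* Planted-feature recovery uses 10 informative among 60 features at
  n = 640 with the cohort's class imbalance. The planted simulator
  standardizes each informative feature's class means to a fixed effect
  size (default 1.5 SD of within-class noise) so that every planted
  feature genuinely separates classes — with raw Gaussian class means an
  "informative" feature can be indistinguishable from noise by chance,
  which no selector could recover. mmRFE runs with `step = 0.1` and
  3-fold CV at this scale; models use 150 trees / 80 boosting rounds,
  which reach the same rankings as the full defaults in a fraction of the
  time at n = 640.
* The null check shuffles labels on 400 balanced noise-only samples and
  requires the pooled CV accuracy to stay inside the central 99% binomial
  band around 0.25.
* End-to-end determinism reruns the full pipeline twice from one seed on
  a 32-case cohort and compares artifact bytes.

## Numerical conventions and degenerate inputs

Population (denominator n) standard deviations everywhere; base-2
entropies; correlation, bias and peak fall back to 0 when a variance
vanishes; a constant ROI patch makes the Otsu threshold undefined and
raises a typed error (`degenerate_threshold_error`), as do empty grown
regions, empty masks, boundaries shorter than 3 pixels, and an all-zero
earlier phase in pixel-wise kinetics. Masks with fewer than one interior
pixel produce an all-zero LBP histogram with a warning rather than an
error, so single-case degeneracies do not kill a cohort run.

## Known limitations

* The feature schema enumerates 146 labels; source descriptions of this
  suite quote 142 or 143 "valid" features, the difference being columns
  that are zero in a given cohort. This package emits all 146 and lets
  `drop_invalid_columns()` shrink the table per run, logging the count.
* GLCM statistics are averaged over the four directions (5 values per
  phase); per-direction emission would quadruple the block and is not in
  the schema.
* The mmRFE selection rule ("max-min accuracy above θ") is a
  formalization of a qualitative robustness requirement; other readings
  (e.g. max mean) are possible and would occasionally pick a different
  candidate iteration.
* Multi-lesion ROIs, 3D growing, pharmacokinetic modelling (Ktrans/kep)
  and clinical-feature integration are out of scope.
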