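# subtyperad

Radiomics pipeline for recognizing breast-cancer molecular subtypes
(luminal A, luminal B, HER-2 over-expressing, basal-like) from multi-phase
dynamic contrast-enhanced MRI (DCE-MRI). The package is aimed at
medical-image-analysis researchers who need a fully reproducible,
parameter-documented implementation of the classical radiomics recipe —
segment, extract, select, classify — with every stage testable against
synthetic phantoms with known ground truth.

The pipeline has four computational stages:

1. **Segmentation.** Seeded region growing inside a rectangular ROI
   annotation. The growth threshold `t*` is determined dynamically from
   the ROI patch by Otsu's method (maximize between-class variance of the
   256-bin histogram); the lesion is the 8-connected component of
   `{I > t*}` containing the ROI-center seed. The classical baseline with
   a preset threshold `T` (accept `p` iff `|I(p) − I(seed)| < T`) is
   included for comparison, and masks are scored with the dice
   coefficient `S = 2|X∩Y| / (|X|+|Y|)`.
2. **Feature extraction.** A fixed 146-value schema per lesion:
   gray-level co-occurrence statistics (energy, contrast, correlation,
   entropy, homogeneity a.k.a. deficit matrix) averaged over the
   directions 0°/45°/90°/135° for each of three phases; 31 retained local
   binary pattern histogram bins {1–15, 240–255} per phase; pixel-wise
   enhancement statistics `R = (I_T − I_t)/I_t` for the phase pairs
   (1,0), (2,0), (2,1); whole-lesion enhancement and absorption rates
   `ER_i0 = S_i/S_0`, `AR_i0 = (S_i − S_0)/S_0·100%`; per-phase intensity
   statistics; and seven normalized-radial-length morphology descriptors.
3. **Feature selection.** Multi-model recursive feature elimination
   (mmRFE): logistic regression, linear SVM, random forest and gradient
   boosting each rank the surviving features, the rank positions are
   summed into a composite order, the composite-worst features are
   removed, and every model's cross-validated accuracy is recorded per
   iteration. The selected subset maximizes the minimum per-model
   accuracy among iterations where all models clear a threshold θ.
4. **Classification.** The four models plus a majority-vote ensemble,
   evaluated by pooled out-of-fold confusion matrices with per-class
   precision/recall/F1 — the per-class view matters because the cohort
   imbalance (183/241/143/70 across the four subtypes) hides minority
   failure in overall accuracy.

Because real subtype-labeled DCE-MRI cohorts are not freely available,
the package ships a phantom generator (`phantom_spec()`,
`generate_cohort()`) producing multi-phase cases with class-dependent
shape irregularity, intra-lesion texture and enhancement kinetics, plus
ground-truth masks and ROI annotations — every claim the test suite makes
is validated against these synthetic cohorts and against brute-force
oracles.

## Worked example

Segment one phantom case and extract its features:

```r
library(subtyperad)

case <- generate_case(phantom_spec(), "D", "demo", seed = 7)
mask <- region_grow(case$phases[[2]], case$roi)   # dynamic Otsu threshold
round(dice(mask, case$truth_mask), 4)
#> [1] 0.9552

fv <- extract_all(case$phases, mask)
round(fv[c("F1", "F2", "T10", "T11", "T12", "M2", "M4", "M6", "M7")], 4)
#>       F1       F2      T10      T11      T12       M2       M4       M6       M7
#>   0.0184   3.6792   2.6739 167.3933   2.0756   0.1746   0.1594   0.6542 650.0000
```

The dice of 0.955 says the grown mask almost coincides with the ground
truth. `T10 = 2.67` is the whole-lesion first-phase enhancement ratio
S1/S0 (a strongly enhancing class-D lesion; `T11` is the same information
as a percentage), low GLCM energy `F1` with contrast `F2 ≈ 3.7` reflects
the heterogeneous intra-lesion texture, and the morphology block shows an
irregular boundary: NRL spread `M2 = 0.17`, roughness `M4 = 0.16`, and
roundness `M6 = 0.65` — far from the value 1 of a circle. `M7` is the
lesion area in pixels.

A full cohort run — simulate, segment, extract, select, classify — from
one seed:

```r
cfg <- pipeline_config(
  spec = phantom_spec(n_cases = 32, image_size = c(96, 96), seed = 1),
  model_params = list(ntree = 60, nrounds = 40),
  step = 0.5, cv_k = 3, seed = 1)
run_pipeline(cfg, "run1")
```

The run directory then holds `manifest.json`, `masks/`,
`dice_report.csv`, `features.csv`, `trace.json`, `subset.txt`,
`report.json` and `run_log.txt`:

```
simulate: 32 cases
segment: mean dice 0.9823
extract: 32 cases x 146 features; removed 0 all-zero columns ()
select: 9 features selected (theta 0.80)
classify: ensemble accuracy 1.0000
```

The phantom classes are widely separated by design, so a small selected
subset classifies them perfectly; rerunning the same config resumes
stages whose inputs are unchanged, and two fresh runs from one seed are
byte-identical. A thin command-line front end over the same functions is
installed at `inst/cli/subtyperad`
(`subtyperad simulate|segment|extract|select|classify|run`).

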