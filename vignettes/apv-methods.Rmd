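---
title: "Multi-regional radiomics and the two-stage ApV classifier: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-regional radiomics and the two-stage ApV classifier: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Structural MRI carries mesoscopic information about Alzheimer-type
neurodegeneration well beyond the classical hippocampal-volume read-out:
texture, intensity-distribution and shape changes appear across many brain
regions, including regions not classically associated with the disease.
`apvtools` implements a pipeline that turns an isotropic T1-weighted-style
volume plus a multi-region label map into a single scalar disease score,
the *Alzheimer's Predictive Vector* (ApV):

1. **Per-region radiomics.** For each labelled region the package computes
   a fixed catalogue of features on the original image and on 8 stationary
   wavelet sub-band channels: first-order intensity statistics, shape
   descriptors, and five grey-level texture-matrix families (GLCM, GLRLM,
   GLSZM, NGTDM, NGLDM).
2. **Screening.** Features are z-scored with parameters estimated on the
   training split only, then screened per feature with a two-group
   Mann-Whitney test and the Benjamini-Hochberg step-up rule; only features
   with FDR-adjusted q < 0.05 reach the model. Clinical scores (MMSE,
   LDELTOTAL, CSF A-beta/tau/p-tau) and age, when supplied, bypass the
   screen and are always offered as candidates.
3. **Sparse model.** An L1-penalized (LASSO) logistic regression with
   10-fold cross-validated lambda reduces the surviving features to a small
   weighted signature. The ApV score of a subject is the linear predictor —
   the weighted sum of its standardized selected features.
4. **Cascade.** Two such stages are chained: stage 1 separates subjects
   without Alzheimer-related pathology (`nADrp`, pooling healthy controls
   with Parkinson's disease and frontotemporal dementia) from those with it
   (`MCI_AD` + `AD`); stage-1 positives are routed to stage 2, which
   separates prodromal (`MCI_AD`) from established (`AD`) disease. Each
   stage thresholds its score at the Youden-optimal point of its training
   ROC.

The pipeline consumes precomputed label maps (e.g. from an automated
segmentation of T1w images into 45 white-matter/subcortical plus 70
cortical regions); it does not perform segmentation, bias correction or
skull stripping.

## The feature catalogue

The default catalogue holds **656 features per region**:

| block | count |
|---|---|
| shape (original channel only) | 8 |
| 9 channels x 18 first-order | 162 |
| 9 channels x 22 GLCM | 198 |
| 9 channels x 11 GLRLM | 99 |
| 9 channels x 11 GLSZM | 99 |
| 9 channels x 5 NGTDM | 45 |
| 9 channels x 5 NGLDM | 45 |

On the 45-region white-matter mask this yields 29,520 features per
subject. The catalogue is a first-class object
(`feature_catalogue()`): channels, families, discretization and the
texture voxel minimum are configurable, and the catalogue's content hash is
stored inside every serialized model so a model can be matched to the
extraction that produced its inputs. A box-counting fractal dimension
(`fractal_dimension()`) is available as an additional shape-type descriptor
but is not part of the default 656-feature catalogue, whose arithmetic is
pinned to the breakdown above.

Key numerical conventions, chosen once and applied everywhere:

* **Wavelets.** One-level separable *stationary* (undecimated) transform,
  coiflet-1 filters, half-sample symmetric boundary extension. Channel
  labels name the filter applied along axes 1-3, so `LHL` is low-pass,
  high-pass, low-pass. A constant region is annihilated by every channel
  containing an H.
* **Discretization.** 32 equal-width bins over the region's own
  min-max range, half-open bins with the last closed; a constant region
  collapses to one level. Texture features therefore see a
  resolution-independent grey-level alphabet, and all intensity-relative
  features are invariant to adding a constant to the image.
* **Texture geometry.** GLCM and GLRLM use the 13 unique 3D directions at
  distance 1; GLCM is symmetrized and each direction is normalized before
  averaging, which makes the averaged matrices invariant under axis-aligned
  rotations and reflections. GLSZM zones and the NGTDM/NGLDM
  neighbourhoods are 26-connected, and only in-region neighbours are
  counted. NGLDM dependence uses grey-level tolerance 0 and dependence
  size = dependent neighbours + 1.
* **Degeneracy guards.** Ratio-type texture features guard their
  denominators at 1e-6; NGTDM coarseness on a flat region returns the cap
  1/1e-6. Regions with fewer than 27 voxels get masked (NA) texture
  values; empty regions mask their whole block. Masked values are imputed
  as 0 *after* standardization, i.e. at the training mean, which is the
  neutral value for a z-scored linear model.
* **Surface area** counts exposed voxel faces; sphericity is
  `pi^(1/3) (6V)^(2/3) / A`. The maximum 3D diameter scans boundary-voxel
  pairs, deterministically thinned to 800 points for very large regions.

## Screening and model fitting

* The screening test is Mann-Whitney by default (Welch's t is available).
  For both groups of size <= 8 without ties the exact null distribution is
  used. Larger samples use the tie- and continuity-corrected normal
  approximation; on untied data an Edgeworth term with the exact excess
  kurtosis of the null U statistic,
  `-(6/5)(n1^2 + n2^2 + n1 n2 + n1 + n2) / (n1 n2 (n1 + n2 + 1))`,
  keeps the worst-case error against exact enumeration near 1e-3 at small
  n.
* The LASSO path runs over a geometric grid from `lambda_max` (the
  smallest penalty that zeroes every coefficient) down three decades, 100
  points. Folds are stratified by class and reproducible from the seed;
  the chosen lambda minimizes the cross-validated binomial deviance
  (`family = "gaussian"` with squared-error loss is available, since a
  squared-error reading of the selection rule is also defensible). glmnet
  provides the coordinate-descent solver; the grid, fold assignment and CV
  loop are owned by this package, and the solver is verified against the
  soft-threshold closed form on orthonormal designs in the test suite.
* Stage orientation is fixed so the disease class has the higher mean
  training score, and the decision rule is `score >= threshold` (ties
  positive). Thresholds come from the Youden index on the training ROC,
  ties resolved toward the smaller threshold. Both conventions are
  arbitrary but must be fixed for reproducible confusion counts.
* The 70/30 train/validation split is stratified per class and seeded.

## Diagnostics and repeatability

`diagnostic_report()` computes the full panel (sensitivity, specificity,
accuracy, NPV, PPV, LR+, LR-, Youden index, diagnostic odds ratio) with a
typed NA flag wherever a denominator is zero — never an error — matching
the usual reporting convention for undefined ratios. For hold-out columns
where only an operating point is available, `balanced_auc()` implements
the `(sens + spec)/2` convention, which equals the trapezoid area of the
single-threshold ROC. `roc_auc()` computes the rank-statistic AUC with
midrank ties, identical to the swept-curve trapezoid. Repeatability uses
the one-way random-effects, absolute-agreement, single-measurement
ICC(1,1) and Bland-Altman bias/limits.

`subset_robustness()` re-evaluates a fitted stage on restricted weighted
sums: the full selected set (`Ftot`), the top-4 |weight| features
(`Ftest4`), all four triples (`Ftest3-p1..p4`) and all six pairs
(`Ftest2-p5..p10`) of that top set — 12 rows, with |weight| ties broken by
feature name so membership is deterministic. Weights stay at their fitted
values; each subset re-derives its threshold by the Youden rule on the
evaluation split.

## The phantom generator

Real cohort images are access-restricted, so end-to-end behaviour is
validated on synthetic multi-region phantoms (`phantom_spec()`,
`make_cohort()`): a central ellipsoid tiled into seeded-Voronoi regions on
a cubic grid, with three independently plantable per-region, per-group
signals —

* **atrophy**: morphological erosion of the region boundary to a target
  volume fraction (plus ~5% per-subject jitter, mimicking segmentation
  variability);
* **intensity**: a mean shift in units of the noise sd;
* **texture**: a correlated Gaussian field made by smoothing white noise
  with a Gaussian kernel whose sd is the requested correlation length,
  rescaled to unit variance.

Everything is bit-reproducible from `(spec, seed)`; subject seeds derive
deterministically from the cohort seed. The reference study condition
(`study_phantom_spec()`) is a 64-voxel grid with 8 regions and signal in
regions 1-3: intensity shift 1.0 noise-sd and atrophy to 70% volume in
`AD`, half that in `MCI_AD`.

What the phantom does *not* emulate: anatomy (region shapes are Voronoi
cells, not brain structures), MR physics (bias fields, k-space artefacts),
scanner/site effects and field-strength differences, age structure, and
disease heterogeneity. Passing the recovery suite therefore shows the
pipeline recovers planted volumetric/intensity/textural group differences
at realistic noise levels — not that it reproduces clinical accuracy on
real cohorts.

## Validation design and problem sizes

The test suite follows a dual-route design: every numerical kernel is
checked against an independent brute-force oracle (pair/run/zone
enumeration for the texture matrices on grids up to 6^3, direct-formula
recomputation for the feature panels, step-up enumeration for BH,
`C(10,5)` enumeration logic for the exact Mann-Whitney p, soft-threshold
closed form for the LASSO, hand ANOVA for ICC(1,1), pairwise comparison
for AUC, pROC as an external cross-check).

End-to-end recovery runs at the study condition's geometry — 60 subjects
per group on a 64^3 grid with 8 regions and 3 signal regions, five seeds —
using a compact original-channel catalogue (first-order + shape), which is
the family pair the planted intensity/volume signals live in; this keeps
the whole suite at desk scale while exercising the full
standardize/screen/fit/threshold path. Expected behaviour: held-out
stage-1 AUC >= 0.9 with >= 80% of selected features in signal regions. On
null phantoms (no planted effect) the FDR screen correctly keeps nothing
and a stage model cannot be built from imaging features alone — by design
this is an error, not a silent guess; the chance-level check therefore
supplies a random age covariate (score candidates bypass screening) and
verifies the held-out AUC is compatible with 0.5. Because a single
36-subject hold-out has Monte-Carlo sd near 0.1 on the null AUC, that
check averages three seeds.

## Known limitations

* The exact 656-feature composition is pinned by construction (breakdown
  above); an independently produced feature list may name or normalize
  individual features differently even where the totals agree.
* Feature extraction assumes the volume/label-map pair is already on an
  isotropic grid (`resample_isotropic()` is provided, trilinear for
  intensities and nearest-neighbour for labels; the interpolation choice
  is a config-visible decision).
* `balanced_auc()` is a reporting convention for single-operating-point
  hold-outs, not an estimate of the full-curve AUC.
* ICC on phantom rescans is near 1 because phantom noise is small and
  perfectly stationary relative to the planted signal; real scan-rescan
  variability (motion, positioning, scanner drift) is not modelled.
* The Youden threshold equals an observed training score, so a training
  subject can sit exactly on the decision boundary; serialized models
  round-trip scores to ~1e-15 relative precision, which can flip such
  boundary subjects only.
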