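---
title: "An ultrasound-radiomics pipeline for thyroid nodule classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ultrasound-radiomics pipeline for thyroid nodule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usradiomics)
```

## What this package computes

`usradiomics` implements a complete radiomic machine-learning workflow for
binary classification of thyroid nodules on 2D B-mode ultrasound: ROI
preprocessing, a filtered feature bank, univariate feature screening,
ADASYN rebalancing, three majority-vote ensemble classifiers evaluated
under nested 4-fold cross-validation, external testing, and nonparametric
univariate statistics for the selected predictors. Because no patient
images are distributed with the study this pipeline follows, a synthetic
cohort generator is a first-class, tested component: it fixes the cohort
composition (102 benign + 40 malignant training cases; 15 + 6 external)
and provides a texture model with controllable malignancy effects, so that
every claim the test suite makes is about the machinery, evaluated on data
whose generating process is known exactly.

## The synthetic nodule model

Each case is a single axis-aligned elliptical nodule (the ROI) on a darker
tissue background. The texture model has three ingredients:

* **Correlated multiplicative speckle.** Gamma noise with shape `speckle_shape`
  (default 30, coefficient of variation about 0.18), blurred by a Gaussian
  point-spread of `speckle_correlation_px` (default 1 px). B-mode speckle is
  correlated at the resolution-cell scale; the blur is applied to the noise
  field only, so lesion edges stay sharp.
* **Benign macro-structure.** Benign thyroid nodules classically show mixed
  or spongiform echotexture. A smooth random modulation field (Gaussian-blurred
  noise, correlation `macro_correlation_px`, default 6 px at 256 px scale)
  darkens the benign base multiplicatively with amplitude
  `macro_heterogeneity` (default 0.5). The modulation is darkening-only:
  spongiform structure is hypoechoic (cystic) patches in an echogenic matrix,
  and a symmetric modulation would saturate the 8-bit range and make the
  classes separable by the intensity maximum alone, which would be an
  artefact.
* **Malignant focal structure.** Malignant nodules have a more homogeneous
  echogenic background (`malignant_macro_factor` defaults to 0) but carry a
  Poisson number (`malignant_focus_rate`, default 6) of small dark circular
  foci (radius 4–6 px, intensity times `focus_intensity_factor` = 0.55,
  fully inside the ROI, overlaps allowed) and speckle dispersion inflated by
  `malignant_speckle_contrast` = 1.4.

The defaults were calibrated once so that, on a default 142-case cohort,
the malignant-class medians of gradient NGLDM dependence count energy and
square NGTDM complexity exceed the benign medians — the ordering reported
for the study's two strongest predictors. This direction match constrains
the texture model meaningfully: a benign class consisting of homogeneous
speckle alone always has the *higher* dependence count energy on the
gradient image, because any second texture population (foci rims) widens
the fixed-bin-number level histogram. The spongiform benign component is
what makes the observed ordering reproducible; it is also the textbook
appearance of benign nodules.

What the generator does **not** model: attenuation, shadowing and
enhancement artefacts, probe/TGC settings, anisotropic resolution cells,
nodule margins and halo, calcifications, and inter-scanner variation. Tests
passing on this generator therefore demonstrate correctness of the
computational pipeline and recoverability of a known texture signal; they
say nothing about clinical discrimination on real images.

## Preprocessing

Images carry physical pixel spacing (mm). Resampling targets the *coarser*
of the two input spacings (down-sampling only, bilinear for images,
nearest-neighbour for masks, which stay strictly binary). If the resampled
mask would exceed 10^7 pixels (texture purpose) or 10^6 (other features),
the target spacing is uniformly coarsened by the smallest factor that
brings the count under the cap; the rule is idempotent. At the package's
desk scales the caps never bind, but the code path is exercised in tests.

Discretization uses the fixed-bin-number rule with 64 levels over the ROI's
own min–max range; a constant ROI maps to level 1. Levels are invariant
under positive affine rescaling of intensities, which decouples the texture
features from overall gain.

## The feature bank

Five filters (identity; central-difference gradient magnitude in intensity
per mm; Laplacian of Gaussian with `log_sigma_mm` = 1.0 mm, truncated at 4
sigma, reflect padding, output shifted to non-negative; square and square
root normalized by the bit-depth maximum) times seven families: intensity
statistics (17 features, computed on continuous filtered intensities),
intensity histogram (10), GLCM (16), GLRLM (10), GLSZM (9), NGTDM (5),
NGLDM (8) — 375 features per case, named
`<filter>__<family>__<feature>`. Filtered images are re-discretized per
filter over their own ROI range.

Conventions, fixed and documented because several are not standardized:

* 2D computation, four direction offsets at distance 1; co-occurrence and
  run-length matrices are normalized per direction and averaged. GLRLM
  count-based features (non-uniformities, run percentage) are computed per
  direction and averaged, since they are not functions of the normalized
  matrix alone.
* GLSZM zones are 8-connected; note that a two-level checkerboard is *two*
  zones under 8-connectivity, not sixteen.
* NGTDM valid pixels are those with at least one in-ROI Chebyshev-1
  neighbour; coarseness is capped at 10^6 for homogeneous ROIs.
* NGLDM uses tolerance alpha = 0 and counts the centre pixel, so dependence
  counts start at 1; dependence count energy is in (0, 1] and equals 1
  exactly when the ROI occupies a single (level, dependence) cell.
* Percentiles everywhere use linear interpolation between order statistics
  (R type 7); variance/skewness/kurtosis of feature families use population
  moments, with zero-variance inputs returning 0.

Every matrix-family feature is verified against an independent brute-force
oracle (pair enumeration, run scans, flood fill, per-pixel neighbourhoods)
on random grids to within 1e-9 relative error.

## Feature screening

Two univariate screens, in order: sample variance (unbiased, raw feature
scale) at least 0.1; then plug-in mutual information with the class label,
estimated in nats after equal-frequency discretization into 10 bins, at
least 0.19. The screen keeps high-MI features: the alternative (literal)
reading — removing features with high MI against the label — would discard
exactly the informative features and is available behind
`selection_config(mi_keep_high = FALSE)` for comparison. The variance
threshold acts as a near-constancy screen on the raw scale; it is not
scale-free, which is documented behaviour rather than an oversight, since
the bank mixes features of very different magnitudes.

## Rebalancing and ensembles

ADASYN (density-adaptive interpolation) is applied to the two training
folds of each rotation only, with beta = 1 and k = 5: each minority point
receives weight proportional to the fraction of majority cases among its k
nearest neighbours, and synthetic points are uniform interpolations toward
random minority neighbours. When the minority region is majority-free the
weights fall back to uniform. Synthetic counts are integer-rounded per
seed point; originals are never modified.

Each model is an ensemble of 16 members made diverse by stratified
bootstrap resampling with per-member seeds — the minimal assumption under
which majority voting is meaningful. Members are random forests (Gini
criterion, 100 trees per member), or SVMs / kNN (k = 5) on a preprocessing
chain fitted on training data only: standardization, PCA keeping 95% of
variance, Fisher-Discriminant-Ratio ranking of components, top 10 kept.
The ensemble label is the strict majority of member votes; an exact 8–8
tie predicts malignant (the conservative clinical default, configurable).
The continuous score is the mean member malignant-class probability.

## Evaluation and statistics

The nested 4-fold plan deals shuffled cases round-robin within class, so
fold class counts differ from the global ratio by at most one case; each
fold is the internal-test fold exactly once, the next fold (cyclically)
validates, the remaining two train. Reported stages: training, validation
and internal-test *mean* average the member-level metrics (16 members x 4
rotations = 64 samples per metric; the signed-rank test against chance
needs this member-level sample, since 4 rotations alone cannot reach small
p-values), and internal-test *majority vote* scores the pooled per-case
votes. External testing pools all 64 members across rotations.

Metrics are percentages with 95% CIs: normal approximation over member
samples for member-mean stages; Wilson score intervals (and a
Hanley–McNeil interval for AUC) for pooled stages. Chance levels are 50
for ROC-AUC/accuracy/sensitivity/specificity and the class prevalences for
PPV/NPV (28/72 with malignant positive). Both class orientations are
reported externally because the two conventions (benign-positive vs
malignant-positive) swap sensitivity with specificity and PPV with NPV.
Univariate feature statistics use exact Mann–Whitney tests where tie-free,
binomial order-statistic CIs for medians, and Bonferroni–Holm adjustment
with stars at 0.05 and 0.005.

## Problem sizes and determinism

The analysis scripts and repeated-seed checks run at 96 x 96 px with ROI
semi-axes 12–24 px and focus radii 2–3 px — the same texture model with
geometry scaled to desk runtime — while keeping the full 142 + 21 cohort
sizes. The default single-run configuration is 256 x 256 px. All
randomness flows from one global seed through named substreams
(`derive_seed`), so cohorts, folds, ADASYN draws and member bootstraps are
individually reproducible and a full re-run is byte-identical.

## Known limitations

* The feature bank is a documented superset of the study's needs, not a
  reconstruction of any commercial bank; absolute feature values depend on
  the stated conventions (binning, merge rule, alpha, percentile type).
* Synthetic effect sizes make the classes nearly separable; internal AUCs
  near 100 on synthetic data are expected and are not a performance claim.
* The MI threshold (0.19 nats) interacts with the plug-in estimator's
  positive bias at small n; at the study's n = 142 the bias is ~0.03 nats,
  small relative to the threshold.
* External-stage p-values are not computed (a single pooled prediction set
  has no replicate sample); CIs are reported instead.
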