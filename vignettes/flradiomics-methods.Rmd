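---
title: "Methods: baseline PET/CT radiomics for time-to-treatment in follicular lymphoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline PET/CT radiomics for time-to-treatment in follicular lymphoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flradiomics)
```

## The problem

Patients with low tumour burden follicular lymphoma (FL) are usually managed
by watchful waiting (WW): therapy is deferred until progression. The time
from diagnosis to the start of systemic therapy (time-to-treatment, TTT, in
months) varies enormously, and clinical indices predict it poorly. This
package implements a complete analysis pipeline that asks whether
quantitative descriptors of the baseline ^18^F-FDG PET scan — radiomic
features of the metabolic tumour burden, of the single hottest lesion, and
of the healthy liver — carry predictive information about TTT.

The pipeline has five fixed stages, each exposed as ordinary functions and
orchestrated by `runPipeline()`:

1. **Segmentation.** A 2 cm spherical reference VOI on the healthy liver
   yields the PERCIST background threshold
   `1.5 x liver mean + 2 x liver SD`; hypermetabolic lesions are the
   connected components of the supra-threshold voxels. Per lesion we record
   MTV (metabolic tumour volume), SUVmax and SUVmean; TMTV is the sum of
   the MTVs.
2. **Feature extraction.** 81 features per subject under a three-region
   scheme (below).
3. **Scanner harmonization.** A per-feature Wilcoxon rank-sum audit between
   the two scanners with Benjamini–Hochberg FDR control, ComBat
   harmonization with the scanner as the single batch factor, a re-audit,
   and exclusion of features that remain scanner-dependent.
4. **Modelling.** Forward-selected linear regression (continuous TTT) and
   radial-kernel SVM (TTT at-or-below vs above the cohort median),
   validated by leave-one-out cross-validation (LOOCV) at one to four
   features.
5. **Survival screen.** Per feature, a median split of the treated subjects
   and a log-rank comparison of the two Kaplan–Meier curves, FDR-adjusted
   across features.

Because no patient data ship with the package, a synthetic phantom cohort
generator (`generatePhantom()`, `generateCohort()`) provides ground-truthed
inputs for every stage, and a feature-space simulator
(`simulateFeatureTable()`, `simulateSurvivalTable()`) exercises the
statistical stages at scale.

## The feature layout

The fixed 81-name registry (`featureRegistry()`) is:

* 17 first-order intensity statistics on the **pooled tumour burden** — all
  lesion voxels of a subject treated as one multiset: mean, population
  variance, Fisher skewness, excess kurtosis, median, minimum, 10th and
  90th percentile, maximum, interquartile range, range, mean absolute
  deviation, robust mean absolute deviation (values within the closed
  [P10, P90] band, about that band's own mean), energy (sum of squared
  SUVs), root mean square, and discretised uniformity and entropy;
* 14 morphological features **averaged over the individual lesions**
  (sphericity and its relatives are undefined on a union of disconnected
  regions): volume, mesh surface area, surface-to-volume ratio, sphericity,
  spherical disproportion, asphericity, compactness, centre-of-mass shift,
  maximum 3D diameter, three principal-axis lengths, elongation, flatness;
* both families on the **lesion containing the global SUVmax**
  (suffix `.SUVmax`);
* the 17 first-order features on the **liver reference VOI**
  (suffix `.liver`) — the morphology of a fixed 2 cm sphere carries no
  information and is dropped;
* the lesion count and the TMTV in cm^3.

The liver block implements the "theft" idea that FDG-avid burden depletes
tracer available to healthy organs, so healthy-liver uptake statistics can
act as an indirect burden readout.

### Numerical conventions

* Moments use population (1/n) normalisation; skewness and excess kurtosis
  of a constant region are defined as 0 so that degenerate regions do not
  propagate NaN into the models.
* Percentiles use the linear-interpolation convention of
  `stats::quantile(type = 7)`.
* Uniformity and entropy discretise SUVs with a fixed 0.25-SUV bin width
  anchored at zero (the usual fixed-bin-size choice for SUV-calibrated
  PET); the width is a parameter (`binWidth`).
* Voxels exactly at the PERCIST threshold are included (closed threshold),
  and lesion connectivity is the 26-neighbourhood; both are conventions the
  source material leaves open, chosen to match common PET hot-spot
  practice, and both are parameters.
* Components smaller than `minLesionVoxels = 3` voxels are discarded: a
  physician reviews and rejects false-positive foci in a clinical reading,
  and a minimum-size rule is the only algorithmic stand-in available.
  Caller-supplied exclusion masks play the same role for physiological
  uptake.
* The SUVmax-lesion tie (two lesions attaining the same global maximum) is
  broken toward the larger MTV, then the lower label.

### Surface area

Mesh surface area comes from a marching-tetrahedra isosurface at level 0.5:
each grid cell is split into six tetrahedra and the in/out pattern of each
tetrahedron contributes 0–2 linearly interpolated triangles. Meshing the
raw binary indicator reproduces the voxel staircase and overestimates the
area of smooth shapes by 25–30% (an axis-aligned face count, available as
`method = "voxel"`, overestimates a sphere by exactly 3/2 in the limit).
The indicator is therefore anti-aliased first with a small Gaussian whose
sigma adapts to the mask's volume-equivalent radius,
`min(0.7, 0.25 + 0.09 r_eff)` voxels. A fixed large sigma shrinks small
blobs so much that sphericity exceeds 1; a fixed small sigma leaves large
balls ~10% overestimated; the ramp keeps digitized-ball sphericity within
about 3% of 1 for `r_eff >= 3` voxels and within 1.5% for `r_eff >= 8`.
Masks so small that smoothing erases the 0.5 level set fall back to the
raw indicator (their surface is genuinely ill-defined at the grid scale).
Spherical disproportion is computed as the exact reciprocal of sphericity,
so the identity `sphericity x spherical disproportion = 1` holds to the
last ulp.

## Harmonization

The audit uses the two-sided Wilcoxon–Mann–Whitney test per feature (exact
enumeration when both scanner groups have at most 8 subjects and no ties,
otherwise the normal approximation with tie and continuity corrections) and
Benjamini–Hochberg adjustment across the 81 features; the same shared BH
routine (`adjustFdr()`) is used by the survival screen.

`combatFit()` / `combatApply()` implement the parametric empirical-Bayes
location/scale model with the scanner as the only batch factor and no
biological covariates: features are standardized by their grand mean
(weighted batch means) and pooled variance; per-batch location and scale
are estimated on the standardized scale and shrunk toward batch-level
normal / inverse-gamma priors by the usual iterative EB scheme (convergence
when the relative change drops below 1e-4, at most 100 iterations, both
exposed); the adjusted value is `sigma/delta* x (z - gamma*) + alpha`.
The implementation agrees with the reference genomics implementation
(`sva::ComBat`) to ~1e-15, which the test suite asserts.

Two properties one might naively expect do **not** hold, precisely because
of the EB shrinkage (and they fail identically for the reference
implementation): the per-feature grand mean is preserved only
approximately (drift below ~2% of a feature SD on null data), and
re-harmonizing an already harmonized table is not a no-op — the second
pass moves values again, though by much less than the first. The tests
assert these achievable contracts. Features with zero pooled variance
cannot be standardized; they are flagged, passed through untouched, and
excluded from modelling. Features still FDR-significant after
harmonization are discarded (`dropUnharmonized()`), and the TTT column
itself is rank-sum tested against the scanner as a confounding check
(reported, not acted on).

## Modelling

Features are z-scored with the sample SD (n−1). Forward selection is
greedy on a full-cohort criterion — R² for the linear model, training
accuracy for the SVM — producing a nested sequence of up to four features;
ties break deterministically by registry order. The selected fixed subsets
are then LOOCV-validated: K fits on K−1 subjects, z-scoring refit within
each training fold and applied to the held-out subject (this prevents a
scaling leak the two-step protocol does not otherwise address). LR test
metrics are pooled RMSE and R² over the K held-out predictions, with R²
defined as 1 − SSE/SST about the held-out outcomes' mean — it can be
negative, and that is meaningful (worse than predicting the mean). SVM
test metrics are pooled accuracy/precision/sensitivity plus the rank-based
(Mann–Whitney, ties one half) AUC of the pooled decision scores, oriented
so the early-treatment class is positive. Training metrics are averaged
over folds.

This select-then-validate order deliberately reproduces the classical
two-step protocol, which leaks selection information into the validation
estimates — the held-out metrics of the later, weaker features are
optimistic, because those features were chosen using the full cohort. The
honest alternative (`nestedSelection = TRUE`) re-selects inside every
training fold. The leak has a visible consequence in simulations at n≈38
with ~80 candidate features: pooled held-out RMSE keeps improving as
features are added even when the extra features are pure noise, so a
"validation peak at small k" is the exception, not the rule, under the
default protocol.

SVM hyperparameters are not dictated by the protocol; the defaults are the
common library choices, `cost = 1` and
`gamma = 1 / (n_features x pooled feature variance)`, both exposed.
Subjects at exactly the median TTT are classed "early" (at-or-below); the
class labels are recomputed on whatever subject subset is analyzed. By
default all subjects enter the models, with never-treated subjects
contributing their follow-up time as the recorded TTT — how censored
subjects entered the regression targets is genuinely ambiguous in this
protocol family, so `treatedOnly = TRUE` is available to restrict to
treated subjects.

## Survival screen

Only treated subjects (all-event data) enter by default. Each feature is
split at its own median over the analyzed subjects — ties go to the
"at-or-below" group, so a heavily tied feature can produce a degenerate
split, which is skipped with a warning rather than tested. The two groups'
TTT curves are compared by the standard log-rank test (chi-square, 1 df)
via the survival package, and p-values are BH-adjusted across the
non-skipped features. At n = 26 (13 + 13, all events) the raw log-rank
test has ~0.74 power against a hazard ratio of 3 at alpha = 0.05, and FDR
adjustment across 81 features can only lower that; a screen of this size
flags only strong, consistent effects.

## The phantom generator

`generatePhantom()` builds one subject: quasi-spherical lesions are placed
as continuous-space spheres (uniform radius 5–12 mm, uniform nominal peak
SUV 6–13) rasterized to a 3 mm grid, on a background of SUV 1.0 with
Gaussian voxel noise (SD 0.15), together with a homogeneous ellipsoidal
liver (mean 2.0, SD 0.25, giving a PERCIST threshold of 3.5); the
noiseless structure is blurred by a 2.5 mm Gaussian point-spread before
noise is added, and the volume is clipped at 0. Placement retries are
bounded, and an impossible packing is an explicit error. Continuous-space
spheres make the morphology ground truth analytic.

`generateCohort()` draws 38 subjects by default, 16 on scanner A and 22 on
scanner B; scanner B applies a gain of 1.1 and an offset of +0.3 SUV *to
the image*, not to the features, so batch effects traverse the entire
extraction path the way real calibration differences would. The outcome is
`TTT = 75 − 0.8 x TMTV − 1.8 x SUVmax + N(0, 15)` months, clamped to at
least 1 (TTT is strictly positive), computed from *noiseless ground-truth*
feature values so that outcome-model recovery is separated from
segmentation error; 12/38 subjects are flagged never-treated with a
follow-up time drawn uniformly on 24–134 months recorded instead. Lesion
counts vary per subject (template ± 4, clamped to ≥ 1). These defaults
reproduce cohort summaries of the intended scale — median ~7–8 lesions,
median TMTV ~25 cm³, median SUVmax ~12.5, median TTT ~40–50 months.

What the phantom does *not* emulate: correlated (reconstruction-textured)
noise, scatter and attenuation artefacts, respiratory motion, physiological
uptake that a physician would reject, anatomical variation in liver
position, and partial-volume effects beyond the Gaussian blur. Passing
tests on the phantom therefore demonstrate the *computational* correctness
and statistical calibration of the pipeline, not clinical performance on
real scans.

The feature-space simulators generate standard-normal features with an
optional common latent factor (`latentCor`) because real radiomic features
are strongly inter-correlated; scanner effects there are a location shift
in SD units and a scale factor, and the outcome is the same linear model.
They are used where hundreds of cohorts are needed (harmonization recovery,
selection recovery, screen calibration) at sizes the imaging path would
make needlessly slow.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run: feature-oracle equivalence on
100 random arrays; 1000 random threshold pairs; harmonization recovery on
20 cohorts of 50 subjects x 81 features; PRESS equivalence on 20 random
designs; selection recovery on 50 cohorts of n = 200 and the small-cohort
regime on 50 cohorts of n = 38; screen power/size on 120 cohorts of
n = 26; and the full imaging pipeline end-to-end on cohorts of 6–38
subjects on a 64 x 64 x 48 grid. These sizes give stable Monte-Carlo
estimates for every property asserted while keeping a full run in the
minutes range on one core.

## Known limitations

* The mesh area estimator is accurate to ~1–3% for blobs larger than a few
  voxels but inherits the ill-posedness of sub-voxel surfaces; tiny
  lesions' shape features should be read with caution (their first-order
  features are unaffected).
* The PERCIST threshold is a global hard threshold: faint lesions below
  liver-derived background are invisible by construction, and merging of
  adjacent hot regions into one connected component is possible at high
  noise.
* ComBat assumes the batch effect is location/scale per feature; it cannot
  remove scanner effects that change a feature's shape or ranking
  structure, which is why the post-harmonization audit and exclusion exist.
* The two-scanner restriction is enforced (a third batch is an error);
  generalizing would need no new mathematics but is out of scope.
* LOOCV estimates have high variance at n≈38, and the default protocol's
  selection leak makes multi-feature test metrics optimistic; for honest
  generalization estimates use `nestedSelection = TRUE`.

## A minimal run

```{r, eval = FALSE}
report <- runPipeline(list(
  phantom = list(nSubjects = 38L, seed = 1L),
  outDir = "artifacts", maxK = 4L))
report$harmonization$nSignificantPre
cvReportTable(report$cv$LR)
subset(report$kmScreen, significant)
```
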