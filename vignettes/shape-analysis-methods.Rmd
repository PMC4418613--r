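---
title: "3D shape analysis of segmented tumors: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D shape analysis of segmented tumors: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymoshape)
```

## The problem

Encapsulated thymomas (Masaoka-Koga stage I) can be resected directly,
while invasive thymomas usually receive neoadjuvant therapy first, so
telling the two apart on preoperative CT matters clinically. Conventional
CT descriptors (size, cystic change, calcification) separate the classes
only weakly. The premise of this package is that the *3D shape* of the
segmented tumor carries additional signal: invasive tumors grow past
their capsule and become lobulated, so quantitative descriptors of
surface irregularity — above all discrete compactness — should
discriminate where intensity-based descriptors cannot.

`thymoshape` implements the full chain: shape features from binary
segmentation masks, univariate screening, backward stepwise logistic
models, leave-one-out cross-validated ROC analysis with DeLong
comparisons, inter-reader agreement, and a synthetic generator (digital
phantoms plus simulated cohorts) that stands in for the CT data, which
were never deposited.

## The five shape features

All features are computed from a `voxel_mask`: a 3D 0/1 occupancy grid
with physical voxel spacing $(s_x, s_y, s_z)$ in mm. With $n$ foreground
voxels:

* **Volume** $V = n \, s_x s_y s_z / 1000$ in mL, and its natural log.
  Tumor volumes are right-skewed; the log is the scale used for
  inference, and mL makes the log-volumes of tumors a few cm across land
  in the low single digits.
* **Surface area** $A$ in cm², by default the area of an iso-surface
  triangulation (below), with the exposed-voxel-face sum as the `face`
  option.
* **Sphericity** $\Psi = \pi^{1/3} (6V)^{2/3} / A$: the area of the
  equal-volume sphere over the actual area; 1 for a sphere.
* **Discrete compactness** $C_d = A_c / A_{c,\max}$ with
  $A_c = (6n - F)/2$ the number of shared voxel faces ($F$ = exposed
  faces) and $A_{c,\max} = 3(n - n^{2/3})$ its maximum for $n$ voxels
  (attained by a cube). A `full` normalization,
  $(A_c - (n-1)) / (A_{c,\max} - (n-1))$, rescales relative to the
  minimal contact of a connected object and is available as an option; a
  single voxel is 1 by convention.
* **3D roundness** $d_{eq} / d_{\max}$, where
  $d_{eq} = (6V/\pi)^{1/3}$ is the equal-volume-sphere diameter and
  $d_{\max}$ the maximum Feret (caliper) diameter, computed exactly over
  all pairs of surface-voxel centers. A `cubic` variant,
  $6V / (\pi d_{\max}^3)$, is provided; the diameter ratio is the
  default because it keeps realistic blob shapes in the 0.55–0.82 band
  where tumor roundness values live, while the cube compresses them
  toward 0.2–0.5.

```{r features}
sphere <- make_phantom("sphere", radius = 12)
extract_features(sphere)
```

## Surface area: why not count faces

Counting exposed voxel faces overestimates the area of a curved surface
by a factor approaching 1.5 (every oblique patch is replaced by an
axis-aligned staircase). A sphericity built on face areas would sit near
0.54 for a perfect sphere — far from 1 and far below the range observed
for real tumors. The `mesh` method therefore triangulates the 0.5 level
set of the *locally averaged* occupancy: the binary grid is replaced by
its 3×3×3 box mean and the iso-surface is extracted by marching
tetrahedra (each grid cell splits into six tetrahedra; within each, the
level set of the linear interpolant is a triangle or quad, so the method
needs no large case table and is easy to verify). The local average is
essential: triangulating the raw 0/1 field places every vertex on an
edge midpoint and still overestimates a digital sphere's area by ~27%,
while the averaged field recovers it to within 1.6% at radius 10 voxels
and 0.1% at radius 20 (measured in the test suite at radii 10/20/40 with
tolerances 5%/2%/1%). Because digitization can leave the measured area a
hair *below* the continuum value, a near-perfect sphere's sphericity can
exceed 1 by a few parts per thousand; `extract_features()` clips it to
the feature's (0, 1] range.

## Anisotropic grids

CT voxels are anisotropic (sub-millimetre in plane, millimetres between
slices). Volume, mesh area, and Feret diameter are computed in physical
coordinates and need no correction. Discrete compactness, however, is
defined on unit cubes, so masks are nearest-neighbour resampled to an
isotropic grid at the smallest spacing component before face counting
(`resample_isotropic`, on by default and configurable). Whether the
original analysis resampled or computed on the native grid is not
documented anywhere we could check; resampling is the choice that keeps
$C_d$ comparable across scanners with different slice thicknesses.

## The statistical pipeline

* **Univariate screen.** Binary covariates: Pearson chi-square without
  continuity correction when all expected cell counts are ≥ 5, otherwise
  Fisher's exact test (two-sided, point-probability method) — the
  standard operationalization of "as appropriate". Continuous features:
  two-sided pooled-variance Student's t (Welch by flag). Constant
  variables are flagged with p = 1 rather than tested.
* **Logistic models.** Maximum likelihood via IRLS (`stats::glm`),
  continuous predictors standardized internally and back-transformed for
  reporting; odds ratios `exp(coef)` with Wald intervals. Near-complete
  separation — any standardized coefficient beyond ±15 — is an error by
  default, because the MLE does not exist; inside the selection and
  cross-validation loops it is demoted to a warning and the last stable
  iterate is used, since huge odds ratios with very wide intervals are
  exactly the regime small surgical cohorts produce and must be surfaced
  rather than crash the analysis.
* **Backward stepwise selection.** Start from all candidates (callers
  pass the variables passing the univariate screen at p < 0.10); remove
  the variable with the largest likelihood-ratio p-value above 0.10;
  after each removal allow re-entry below 0.05. Ties break by candidate
  order, so input order can affect the trace but not, generically, the
  final model. Re-entry into a previously visited model state is
  blocked, which guarantees termination even at degenerate thresholds
  (`p_remove = 0` walks down to the intercept-only model). Collinearity
  among the retained variables is checked by VIF = $1/(1-R^2)$ against
  the conventional limit of 10.
* **LOOCV and ROC.** Each subject is scored by a model fit on the other
  n−1; by default the variable set is selected once on the full data and
  refit per fold (matching how a single final model is usually
  reported), with `selection_in_fold = TRUE` as the stricter variant.
  The pooled out-of-fold scores give the ROC (threshold convention:
  score ≥ threshold predicts invasive); the AUC is the Mann-Whitney
  pair-count with ties at 1/2; correlated AUCs are compared by the
  DeLong placement-value estimator, cross-checked in the tests against
  both brute-force pair counting and an independent implementation.
* **Agreement.** Two-way random-effects, absolute-agreement,
  single-rater ICC from the two-way ANOVA mean squares, with the
  standard F-based interval and the usual bands (≤0.40 poor, ≤0.60
  moderate, ≤0.80 good, above that excellent). Absolute agreement (not
  consistency) is the right form for two readers who must be
  interchangeable.
* **Sample size.** Fisher-z: $n = \lceil ((z_{\alpha}+z_{\beta}) /
  \operatorname{atanh}\rho_0)^2 + 3 \rceil$, floored at 4. The sidedness
  of the original calculation is not stated; the one-sided form is the
  default because it yields n = 16 at $\rho_0 = 0.60$, $\alpha = 0.05$,
  power 0.80, the size actually used for the agreement sub-study, while
  the two-sided form gives 20. Flagged prominently here because the two
  conventions genuinely differ.

One behavior worth knowing: pooled LOOCV scores are *pessimistically*
biased under the null. Leaving a subject out pulls the refit away from
that subject's label, so an uninformative feature yields a mean
cross-validated AUC well below 0.5 (≈ 0.24 at n = 30 in our tests), not
0.5. The tests therefore assert the absence of optimism rather than a
null AUC of 0.5. Informative features are unaffected (a separable
feature still reaches AUC 1).

## What the synthetic data emulate — and what they do not

`simulate_cohort()` draws, per class, binary covariates at the published
prevalences (cystic change 3/23 vs 16/30, calcification 4/23 vs 7/30,
symptoms 2/23 vs 9/30, myasthenia 4/23 vs 7/30) and continuous features
from normal distributions with the published means/SDs, with bounded
features resampled into (0, 1] (resampling, not clipping, to avoid point
masses at the bounds; the resulting population mean is the
truncated-normal mean, which the tests use as the oracle). Features are
drawn *independently within class* because no covariance structure was
published; an optional correlation can be injected by the caller, but
the default cannot reproduce, e.g., the volume–surface-area dependence
of real tumors. Consequently the simulated cohorts reproduce the
univariate screening pattern (cystic change and discrete compactness
significant in the majority of seeds) and the qualitative model ordering
(combined > shape > clinical AUC), not the originally reported
multivariable coefficients.

`make_phantom()` rasterizes spheres and ellipsoids, and adds lobulation
as seeded Gaussian radial bumps: the surface radius is multiplied by
$1 + \sum_j a \exp(-\theta_j^2 / 2w^2)$ over `n_lobes` random
directions. The surface stays star-shaped, so the object is always one
26-connected component. Many narrow lobes (the cohort generator uses 10
lobes of width 0.25 rad) are what depress discrete compactness; a few
broad bumps change roundness and sphericity but barely touch $C_d$.
At desk-scale radii (7–16 voxels) the attainable $C_d$ range is narrow
(≈ 0.91–0.99) because the compactness deficit of a blob scales like
$1/r$; the published tumor range (0.37–0.93) belongs to much larger
voxel counts. The phantom experiments therefore test *orderings and
separations*, never the absolute feature moments of real tumors.

`make_phantom_pair()` emulates two readers segmenting the same tumor.
The second mask erodes/dilates boundary voxels with a per-voxel
probability proportional to `rater_noise` and modulated by a smooth
random angular field, so disagreement arrives as coherent over- or
under-inclusion of whole boundary regions — the way human contours
differ. Independent per-voxel flips were rejected: they roughen the
digital surface so severely that the face-derived features lose all
inter-reader agreement at any useful noise level, which contradicts the
excellent agreement (ICC 0.94–0.99) reported for trained readers and
would make the agreement module untestable.

All generators are pure functions of (spec, seed); per-phantom sub-seeds
are counter-based so adding a subject does not shift the others.

## Numerical choices and degenerate inputs

* Empty masks are errors for every geometry operation; single-voxel
  masks return $C_d = 1$ by convention, Feret 0, and fall back to the
  face area under the mesh method (with a warning).
* Multi-component masks are reduced to the largest 26-connected
  component with a warning (stray voxels are common in manual
  segmentations); labeling is a vectorized breadth-first flood fill.
* Zero cells in a 2×2 table get the Haldane–Anscombe 0.5 correction,
  flagged in the result; empty margins are errors.
* IRLS runs to `epsilon = 1e-10` with at most 100 iterations;
  convergence and iteration count are part of the fit object, and the
  log-likelihood is non-decreasing across iterations (tested).
* `write_feature_table()` emits 17 significant digits so feature CSVs
  round-trip to 1e-12.

## Problem sizes used by the tests and the acceptance script

The suite runs digital spheres up to radius 40 for the convergence
checks, 500 null replicates at n = 200 for the DeLong type-I
calibration, 100 seeds at n = 200 for the stepwise retention check, and
50 seeded phantom cohorts of 10 + 10 subjects (radius 7–11 voxels,
lobulation gap 0.5, face-method features) for the end-to-end ordering
check; `scripts/acceptance.R` repeats the same computations at 20
end-to-end seeds. These sizes were chosen as the smallest at which the
checked quantities are stable across seeds.

## Known limitations

* The exact formulas behind the original in-house software are only
  partially documented; the surface-area estimator, the $C_d$
  normalization and the roundness variant implemented here are the
  standard published forms, exposed as configuration so they can be
  revisited against the original definitions if they surface.
* Within-class feature independence in the cohort generator (above).
* The AUC confidence intervals printed by the original study are
  narrower than DeLong intervals can produce at n = 53; the original
  interval method is unknown, so DeLong is used and AUC CIs are treated
  as descriptive, not as reproduction targets.
* DICOM series reading, registration and segmentation itself are out of
  scope; masks are taken as given in NIfTI or NRRD.
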