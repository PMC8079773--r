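---
title: "Methods: radiomic outcome modelling for recurrent glioblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic outcome modelling for recurrent glioblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiogbm)
```

# The analysis problem

Recurrent glioblastoma presents on gadolinium-enhanced T1-weighted MRI as a
contrast-enhancing lesion, often with cystic or necrotic components and a
resection cavity from prior surgery. `radiogbm` models three endpoints from
quantitative descriptors of this lesion and of a 15-mm peritumoral rim:
the binary *MGMT* promoter methylation status (logistic regression),
progression-free survival from first salvage therapy (PFS₂) and overall
survival (OS) (Cox proportional hazards). Multi-center MR intensities have
no common scale, so every quantitative step is preceded by explicit
geometric and intensity standardization, and every modelling step obeys a
strict training/validation separation.

This vignette explains each stage, its assumptions and tunable parameters,
the numerical conventions, and what the synthetic data generator does and
does not emulate.

# Geometry

**Grids and masks.** All images are axis-aligned scalar lattices with
per-axis spacing in mm (`voxel_grid`); regions are binary masks aligned to
their grid within 1e-3 mm on spacing and origin (`voi_mask`). The 1e-3 mm
tolerance absorbs file-format float noise while rejecting genuine
mismatches; oblique acquisitions are rejected at read time rather than
silently resampled.

**Peritumoral rim.** The rim contains every voxel whose centre lies within
`distance_mm` (default 15 mm) of some tumor voxel centre, minus the tumor
and all exclusion regions. Distances are Euclidean in world millimetres,
computed with a separable lower-envelope distance transform that honours
anisotropic spacing — clinical slice thickness spans roughly 0.4–6.6 mm,
so a voxel-count dilation would be badly wrong in the slice direction.
Whether "15 mm" should be measured from voxel centres or from a surface
mesh is underdetermined; centre-to-centre is implemented because it has an
exact lattice ground truth (the rim of a single voxel is a discrete ball,
which the tests enumerate directly). The rim is built on the native grid,
before any resampling, since segmentation precedes normalization in the
workflow.

**Minimum volume.** VOIs smaller than 0.2 ml (1 ml = 1000 mm³) are flagged
for exclusion; the comparison is strict (`< 0.2 ml`), so a VOI of exactly
0.2 ml is kept.

# Preprocessing

**Resampling.** Trilinear interpolation to cubic 1 mm for shape analysis
and cubic 3 mm for intensity/texture analysis. The target lattice keeps
the source origin and never extrapolates; masks are interpolated as
indicators and cut at 0.5 (values ≥ 0.5 are inside). Trilinear
interpolation reproduces affine intensity fields exactly, which the tests
exploit as an oracle.

**Intensity normalization.** Two schemes, compared throughout:

* *Fixed bin number* — the in-VOI intensity range is split into `n_bins`
  (default 32) equal bins; `level = 1 + floor(n_bins (I − I_min) / (I_max −
  I_min))` with the maximum mapped into the top bin. The output is
  invariant to any orientation-preserving affine transform of the
  intensities, which is the entire point: scanner gain and offset cancel.
* *Two-point linear rescaling* — the affine map sending the mean of a
  white-matter reference region to `anchor_wm` and the mean of a
  vitreous-body reference to `anchor_vitreous` is applied to the whole
  volume, then intensities are discretized with a fixed bin width
  (default 50), anchored at the in-mask minimum. The anchors are
  configuration parameters with defaults vitreous → 0 and white matter →
  300: declared package defaults (not values inferred from any external
  source) chosen so that typical enhancing-lesion contrast spans roughly
  30–35 grey levels at bin width 50, keeping the two schemes' level counts
  comparable — a large disparity in level counts would make their texture
  values incomparable through differential noise sensitivity. Applying
  the normalization twice is idempotent, and any affine scanner
  distortion of the input yields a bit-identical normalized volume.

Discretization is per VOI (tumoral and peritumoral independently), because
features are reported per VOI; the choice of in-mask minimum as the
fixed-bin-size anchor is recorded in the feature provenance so it can be
switched to a global constant if a cross-VOI-comparable scale is ever
needed.

# Feature extraction

Each VOI yields exactly **180 features: 24 shape + 19 intensity + 137
texture**. Wavelet-filtered features are deliberately absent (the analyzed
regions are too small for stable wavelet statistics).

**Shape (24).** Computed on the 1 mm mask. Surface area and mesh volume
come from a marching-tetrahedra triangulation of the 0.5-isosurface of the
mask smoothed with an isotropic Gaussian of σ = 1 voxel. The smoothing is
essential: a midpoint mesh of raw binary data overestimates the area of a
digital ball by tens of percent (the staircase artifact), while the
smoothed mesh recovers a radius-10 mm ball's area to a few percent. Volume
is accumulated from the same closed, outward-oriented mesh by the
divergence theorem, so mesh volume and area always satisfy the
isoperimetric inequality and sphericity is ≤ 1 *by construction*.
Principal-axis lengths are `4 sqrt(eigenvalue)` of the voxel-centre
covariance (population convention), matching the analytic `a²/5`
covariance of a uniform ellipsoid. Very small masks (a handful of voxels)
can have an empty smoothed isosurface; their mesh-derived features are 0
and flagged degenerate rather than NaN.

**Intensity (19).** Population moments (kurtosis is excess kurtosis;
normal ⇒ 0), order statistics, robust dispersion, histogram energy and
entropy on the discretized levels, and intensity–volume-histogram
fractions ("enhancing tumor volume X%" = fraction of VOI voxels strictly
above X% of the in-VOI range) for X ∈ {30, 40, 70}. On the fixed-bin-number
branch the features operate on the bin levels (the binning *is* the
normalization); on the linear branch, on the rescaled intensities.

**Texture (137).** Six 3D matrix families at 26-connectivity / Chebyshev
distance 1: co-occurrence (GLCM), run length (GLRLM), size zone (GLSZM),
distance zone (GLDZM; zone distance = city-block distance to the VOI
border, border voxels at distance 1), grey-tone difference (NGTDM) and
grey-level dependence (NGLDM; dependence coarseness α = 0, i.e. a
neighbour is dependent only when its level is exactly the centre level,
and the count includes the centre voxel, so a fully uniform 27-voxel
neighbourhood has dependence 27). GLCM and GLRLM are aggregated two ways —
all 13 unique directions merged by summation, and features averaged over
per-direction matrices — because both aggregations are in common use and
their disagreement is itself informative. The census is 25 GLCM × 2 + 16
GLRLM × 2 + 16 GLSZM + 16 GLDZM + 5 NGTDM + 18 NGLDM = 137; the NGLDM set
is the 17 standard descriptors plus the mean dependence count. The exact
composition of a published 137-feature list is not recoverable, so this
package fixes the census by construction and guarantees that every
feature named in the recurrent-glioblastoma literature it mirrors (NGTDM
busyness, NGLDM low dependence emphasis, GLSZM zone size entropy and large
zone low grey level emphasis, GLRLM long runs emphasis and run length
variance, kurtosis, coefficient of variation, histogram energy, enhancing
tumor volume 30/40/70%, minor axis) is present under a stable name
(`feature_aliases()`).

**Degenerate conventions.** Entropies of one-cell distributions are 0;
0/0 ratios are 0; NGTDM coarseness of a flat region is capped at 1e6;
GLCM correlation with zero marginal variance is 0; busyness with a zero
denominator is 0. A constant VOI therefore produces a complete, finite
feature vector with degeneracy flags, never NaN — this matters because a
single NaN would poison the downstream PCA.

**Oracle testing.** Every matrix family and all 137 features are verified
against independent brute-force implementations (scalar loops straight
from the definitions) on randomized volumes up to 5³ with up to 4 grey
levels, at 1e-9 relative tolerance; merged features are additionally
checked to be invariant under lattice rotations and VOI translation.

# Feature selection

Features are standardized to training mean 0 / variance 1; constant
training columns are dropped and logged; the *training-derived* transform
is applied verbatim to validation data. The correlation-matrix eigenvalues
are compared with per-rank 95th-percentile eigenvalues of standard-normal
data of the same shape (Horn's parallel analysis; default 1000 null
simulations, seeded); counting stops at the first component that fails.
Each feature is assigned to the retained component on which its squared
loading — its contribution to that component's variance — is greatest,
ties to the lowest index. Within each group a univariable model per
feature (logistic or Cox) supplies a Wald p-value and a discrimination
metric (AUC of the fitted score, or the fitted model's concordance, which
is ≥ 0.5 by construction since the coefficient sign absorbs direction);
the best significant (p < 0.05) feature represents the group, ties broken
by smaller p then name. No multiple-testing correction is applied: the
group structure is the redundancy control, by design. Screening operates
on the scaled features, consistent with scaling preceding grouping.
If Horn retains nothing (a pure-noise spectrum), the pipeline falls back
to a single all-features group rather than aborting.

# Outcome models

The group representatives enter a multivariable logistic or Cox model;
greedy backward selection repeatedly drops the variable whose removal
lowers the AIC most (`stats::step` with intercept-only/null lower scope).
Selection may legitimately reach the empty model; that branch is then
reported as "no model", an expected scientific outcome, not an error.
Binary models are evaluated by the Mann–Whitney AUC (ties half credit)
with DeLong 95% intervals; survival models by Harrell's concordance over
censoring-aware comparable pairs with normal-approximation intervals from
the asymptotic variance. Risk stratification uses the *median training
prediction* as threshold (the deterministic reading of an "optimal
threshold defined as the training median"); the high-risk group is
*strictly greater* than the threshold; groups are compared by two-group
log-rank. The stratified 5-fold cross validation re-runs scaling, Horn
retention, grouping, screening and fitting inside every training fold —
refolding only the final fit would leak selection information, so the
full refold is the defensible reading. Patients with missing MGMT status
are excluded from the MGMT branch only; they keep contributing to the
survival branches.

# Image quality

Per scan: voxel dimensions and slice thickness; repetition/echo time
passed through from metadata (no pulse-sequence modelling); foreground
mean, range and SNR (= foreground mean / background SD) with the
foreground found by exhaustive-search Otsu thresholding of the volumetric
histogram; and the entropy focus criterion, the Shannon entropy of
normalized voxel magnitudes divided by its maximum `log(N)`, so EFC ∈
[0, 1] and is invariant to global intensity scaling. Cohorts are compared
per metric with the two-sample Kruskal–Wallis test. A rank test addresses
distributional location, not variance; because cohort *variability* is
often the quantity of interest, a second mode applies the same test to
absolute deviations from each cohort's median (a rank-based dispersion
test), and the pipeline reports both rather than guessing one reading.

# The synthetic data generator

**Phantoms** are axis-aligned ellipsoids and boxes only — an enhancing
tumor shell with a concentric necrotic core, white-matter and
vitreous-body reference boxes, an optional resection-cavity-like exclusion
box — with Gaussian noise and a scanner affine gain/offset applied to the
aligned pre/post-contrast pair. The austerity is deliberate: every mask
has an analytic volume, surface and distance ground truth, so geometry
tests are exact. Phantoms do *not* emulate brain anatomy, partial-volume
tissue mixtures, bias fields (deliberately out of scope), motion or
Rician noise; passing phantom tests therefore demonstrates correctness of
the *operations*, not segmentation robustness on real data.

**Cohorts** draw per-patient latent group scores `z ~ N(0, 1)` and
features `sqrt(rho) z + sqrt(1 − rho) ε`, giving exact within-group
correlation `rho`; the binary label follows a logistic model on the latent
scores, event times exponential proportional-hazards models, censoring
uniform on `(0, T_max)` with `T_max` solved by root finding so the
realized censoring fraction hits its target in expectation. Effects act
on latent scores so "one informative group" is well defined while all its
features stay exchangeable. The defaults are the study conditions the
package mirrors: 69 training and 33 validation patients with known binary
status (the validation cohort's missing-status patients are simply not
generated), seven latent groups of ten features at rho = 0.7, a single
informative group whose *feature-level* theoretical AUC is 0.67 (the
published training/validation AUC of the MGMT model), a ~41% marginal
prevalence, exponential baselines matching median PFS₂ 2.7 and median OS
11.3 months, survival effects at a latent concordance of 0.6 (the
published concordance range), and a 10% censoring target (the observed
event fractions). Effect sizes are calibrated once by closed quadrature
(`theoretical_feature_auc`, `theoretical_latent_concordance`), not by
simulation, so the calibration itself is deterministic. What the cohort
generator does not emulate: real radiomic feature distributions (heavy
tails, hard zeros), feature–feature correlation across groups, and any
dependence of censoring on covariates.

# Numerical choices and problem sizes

* Grid alignment tolerance 1e-3 mm; texture tolerance against oracles
  1e-9 relative; all entropies base 2 (except EFC, which uses natural log
  in both numerator and denominator, where the base cancels).
* All randomness flows through one base seed expanded per stage by a
  polynomial rolling hash into 31-bit sub-seeds, so any stage can be
  reproduced in isolation and no two stages share a stream.
* Horn null eigenvalue quantiles depend only on the data shape and are
  cached/reusable across repeated fits of the same shape.
* The test and acceptance simulations use sizes chosen to make
  Monte-Carlo bands decisive at desk scale: 200 random ≤ 5³ volumes for
  oracle equivalence, a 40³ exhaustive rim check, 200 seeds for Horn
  recovery (200×40) and noise rejection (60×40), 1000 null simulations
  for the log-rank size (true size measured at ~5% for the n = 100,
  one-third-censored configuration), and 200 simulated 69/33 cohorts for
  end-to-end recovery.

# Known limitations

* Only axis-aligned volumes are supported; oblique data must be
  resampled upstream.
* The marching-tetrahedra mesh under σ = 1 smoothing slightly erodes
  sharp corners, so mesh volume under-reads the voxel volume by a few
  percent on cubes; both volumes are reported side by side.
* The 137-texture census is fixed by construction (see above); it cannot
  be byte-compatible with any particular external extractor's private
  feature list, only with the named features and the count.
* Cox models assume proportional hazards; the simulator generates data
  that satisfy it, so tests do not probe violations.
* With 69 training patients and a true AUC near 0.67, univariable
  screening at p < 0.05 has limited power; a fraction of simulated runs
  legitimately end in "no model", exactly as a branch of the mirrored
  analysis did.
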