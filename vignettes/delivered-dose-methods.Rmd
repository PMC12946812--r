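---
title: "Delivered-dose accumulation and bowel-cavity motion analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delivered-dose accumulation and bowel-cavity motion analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtaccum)
```

## The problem

Pelvic radiotherapy for rectal cancer is delivered over ~5 weeks (50 Gy in
25 fractions is the course modelled here).  Day-to-day changes in the
bowel — especially the volume and position of intraluminal gas, the
*bowel cavity* (BC) — alter both bowel geometry and the electron-density
map the dose calculation sees.  The planned dose is therefore not the
delivered dose: episodic gas distension reduces attenuation upstream of the
target and displaces bowel loops into hotter dose envelopes, selectively
inflating high-dose metrics (PTV D2%, whole-bowel D0.03cc) while
near-minimum target coverage (D98%) is largely preserved.  `rtaccum`
implements the full analysis chain for quantifying this effect —
per-fraction dose recalculation, deformable dose accumulation with QA
gates, DVH endpoint differencing, motion-dose association statistics, and
logistic NTCP risk estimation on whole-bowel V45 — and, because clinical
image sets of this kind cannot be redistributed, pairs it with a synthetic
pelvic-phantom cohort generator that realises controlled bowel-gas motion
with a known ground-truth deformation field.

## Synthetic cohort

`phantom_spec()` describes a desk-scale pelvis on a 64 x 64 x 48 grid at
4 mm isotropic spacing (a deliberately coarser sampling than clinical CT;
the whole geometry scales down further with the `scale` argument so test
suites can run on 32-voxel grids).  The layout is analytic: an elliptic
body contour, a ~1170 cc PTV ellipsoid (the realistic target volume for
rectal-cancer planning including nodal regions), a bladder sphere, a rectum
tube, two femoral heads plus a sacral promontory (bone, HU 700 — their
centres double as the rigid-registration landmarks), and a whole-bowel
region superior-anterior to the PTV that hosts spherical gas pockets
(HU -950).  Masks are carved to pairwise disjointness with priority
PTV > bladder > rectum > bone > bowel, and gas is by construction a subset
of the bowel label.  Gaussian HU texture (soft tissue 35 +/- 12 HU, gas
-950 +/- 30 HU) makes the segmentation surrogate non-trivial; setting the
noise SDs to zero gives the exact piecewise-constant phantom used by the
identity tests.

A fraction anatomy realises a requested relative BC volume change
`target_dvbc` by scaling the pocket radii.  Because voxelised volumes are
step functions of radius, the radii are solved by a secant iteration with a
local refinement, falling back to per-pocket adjustment on coarse grids;
the realised change is stored alongside the request and the generator
guarantees agreement within 3 percentage points over requests in
[-30%, +80%] at the default grid (tested).  The ground-truth deformation
field is the analytic radial expansion of each pocket: inside a pocket the
map is a linear stretch of the sphere; outside it follows the
volume-preserving far field `r' = (rho^3 + b^3 - a^3)^(1/3)`, smoothly
tapered to zero over 45 mm so that bone (and hence the landmarks) stays
rigid and organ boundaries away from the pockets move by less than a voxel.
Bladder-volume jitter uses the same radial machinery, with its radius also
solved against the voxelised volume so the realised change respects the 5%
stability cap that defines the modelled cohort; the external contour is
held fixed (8% cap trivially satisfied).  These caps mirror the selection
criteria of the modelled study population.

No clinical distribution of per-fraction BC change is published for this
setting, so the cohort sampler is explicit about its choices and makes them
configurable: per-patient mean change is uniform on [-10%, +60%] and
per-fraction noise is Gaussian with SD 12 percentage points.  That choice
creates both between-patient variance (needed by the patient-level
regressions) and within-patient variance (needed by the fixed-effects
models); it is a modelling convenience, not a claim about any clinical
cohort.  `generate_cohort()` returns *skeleton* course records — the full
sampling plan plus per-fraction seeds — from which any anatomy is
regenerable bit-identically; materialising all 700 anatomies of a default
course at once would cost several GB of memory for no benefit.

## HU to electron density

The calibration is a three-segment piecewise-linear map: air
(-1000 <= HU < -200), soft tissue (-200 <= HU < 300) and bone
(300 <= HU <= 1500) each multiply a base anchor curve by a scanner-derived
factor, defaulting to 0.995 / 0.977 / 0.972.  The base anchors
((-1000, 0.001), (-200, 0.82), (0, 1.0), (300, 1.15), (1500, 1.85)) are a
standard CT-calibration shape; they are configurable because the exact
clinical base table is vendor-internal.  Two completions were genuinely
open and are resolved as follows:

* **Factor semantics.** The factors are treated as mean dose *ratios*
  (reference / recalculated) per HU segment, i.e. the multiplicative
  correction that nulls the mean dose difference in that segment —
  consistent with their role as scaling factors.
  `derive_segment_factors()` implements exactly this estimator and a
  round-trip test recovers constructed factors to three decimals.
* **Continuity.** Piecewise constant factors alone would produce jumps at
  -200 and 300 HU; the factor field is therefore cross-faded linearly over
  +/- 25 HU around each breakpoint.  Monotonicity of the final curve over
  [-1000, 1500] is verified at construction time and the constructor
  refuses non-monotone inputs.

HU values are clamped to [-1000, 1500] before lookup, and the output is
floored at a small positive density so downstream ray integrals stay
finite.

## Dose engine

The dose engine is deliberately *not* a clinical convolution algorithm: it
is a transparent exponential-attenuation model whose only physical
obligations are determinism and density sensitivity in the correct
direction.  Twelve coplanar beams at equispaced gantry angles (matching the
modelled IMRT technique's field count) each contribute
`aperture(v) * exp(-mu_eff * d(v))`, where `d(v)` is the water-equivalent
depth obtained by ray marching from the beam source (source-axis distance
1000 mm) with sub-voxel steps (spacing/2) and trilinear density sampling,
and the aperture is a rectangular jaw fitted to the PTV projection plus a
7 mm margin with a sigmoid penumbra (sigma 6 mm).  `mu_eff` defaults to
0.005 per mm, a 6 MV-like effective falloff.  The planning call solves the
global scale so the median PTV dose equals the 2 Gy per-fraction
prescription; per-fraction recalculations reuse the *planning* scale,
mirroring fixed monitor units at delivery — renormalising each fraction
would silently cancel part of the density signal the study is about.
Scatter, couch and leaf sequences are out of scope.

The physical behaviour that matters downstream is tested directly: depth
dose is monotone along a beam in homogeneous density, enlarging gas volume
never decreases PTV D2%, and switching the pocket density from
soft-tissue-equivalent to gas raises D2% and D0.03cc while leaving D98%
essentially unchanged — the selectivity pattern the analysis chain is
designed to detect.

## Warping, QA gates and accumulation

Fraction doses are mapped to planning geometry by pull-back (backward)
warping with trilinear interpolation: the value at a planning voxel is the
fraction dose sampled at `planning point + displacement`.  Pull-back is
the standard, mass-agnostic choice; energy/mass-conserving dose mapping is
deliberately not claimed.  Out-of-grid samples contribute 0 Gy and are
counted, with a warning past 1% of voxels.  In synthetic runs the
registration DVF defaults to the generator's ground truth, optionally
perturbed with Gaussian noise (`dvf_noise_mm`) to exercise the QA gates;
no learned registration is implemented.

Every fraction passes two gates before it may enter the accumulation:
landmark target registration error (sacral promontory + femoral heads)
at most 3 mm, and a gamma pass rate (2%/2 mm, global normalisation) of at
least 90% between the warped dose and the reference recalculated dose
inside the pelvic ROI (body mask restricted to slices within 5 mm of the
PTV).  Failures invoke an optional retry hook up to `max_retries` times and
are then flagged for exclusion — a result, not an error.  Accumulation is
an element-wise sum over accepted fractions, with linearity and a
summation-oracle test pinning the arithmetic.

Rigid alignment of the bony landmarks (six degrees of freedom) is a
closed-form least-squares fit (Kabsch); the synthetic generator emits
fractions already couch-corrected, so the rigid stage is exercised by its
own generate-and-invert tests rather than inside the default pipeline.

## Gamma analysis

The gamma implementation is global-normalisation: the dose criterion is a
percentage of the *reference* maximum (so the comparison is intentionally
asymmetric — tested), the low-dose cutoff defaults to 10% of that maximum,
the spatial search extends to 3x the distance-to-agreement with a step of
DTA/5, and the evaluated dose is interpolated trilinearly at each probe.
These completions (normalisation mode, cutoff, search discretisation) are
conventional choices where only "2%/2 mm" is specified, and all are
configurable.  The compiled search sorts probe offsets by distance and
exits early once the distance term alone exceeds the current minimum,
which makes identical-distribution comparisons effectively free; a plain-R
brute-force oracle over the same probe set verifies identical per-voxel
pass/fail decisions on 16^3 grids.

## DVH endpoints and differences

DVHs are cumulative (volume receiving at least d), built by direct voxel
sampling at 0.05 Gy bins; at 4 mm voxels the sampling error is far below
the reported precision, and a refinement test checks that halving the bin
width moves endpoints by less than a bin.  Dose-at-volume queries invert
the curve by linear interpolation; D0.03cc is explicitly sub-voxel on
coarse grids and relies on that interpolation (documented behaviour, tested
for refinement stability; whether the clinical system interpolated or took
nearest-voxel values is unknowable from outside).  A volume query at or
beyond the structure volume (D150cc on a structure smaller than 150 cc,
as happens on scaled-down phantoms) returns the structure minimum dose.
The endpoint family is
PTV D2%/D50%/D98% and whole-bowel D0.03cc/D150cc, plus whole-bowel V45
(cc).  Differences are `delta = delivered - planned` in Gy and
`delta_pct = delta / planned x 100`.

Per-fraction endpoint deviations are computed on the fraction dose scaled
to course-equivalent (x 25), so per-fraction and accumulated deviations
share units and magnitude with the published course-scale tables; the
patient-level per-fraction summary is the within-patient median across
fractions.  Cohort tables report medians with percentile-bootstrap 95% CIs
(2000 resamples) and counts exceeding |delta| thresholds of 0.5/1/2/3 Gy
and |delta_pct| thresholds of 1/2/3%.

## Bowel-cavity segmentation surrogate

Clinically the BC is contoured by auto-segmentation plus expert editing;
in silico the surrogate is a threshold rule: voxels inside the whole-bowel
label (excluding rectum, and stomach when present) with HU below -200,
cropped cranio-caudally to the PTV bounding box +/- 5 mm (inclusive, in
world mm).  The -200 HU threshold is the air-segment boundary of the
calibration curve, far above the ~-900 HU of true intraluminal gas, so the
surrogate is robust to the phantom's HU noise.  A round-trip property links
the modules: segmenting fractions generated at a requested volume change
recovers that change within 3 percentage points.  The patient-level motion
statistic is the median across the 25 per-fraction relative changes.

## Association statistics

For each endpoint the package reports three views of the motion-dose
association, mirroring the published table layout:

* **Spearman rho** between patient-level median BC change and accumulated
  endpoint deviation, with a bias-corrected and accelerated (BCa)
  bootstrap 95% CI (2000 resamples; bias correction from the bootstrap
  distribution, acceleration from the jackknife).  BCa is the strictest
  reading of "bias-corrected bootstrap"; the resample count matches the
  published analysis.
* **OLS slope in Gy per 10% BC expansion** (the predictor is rescaled
  before fitting) with HC3 heteroskedasticity-consistent intervals on
  t(n-2); a coverage simulation in the acceptance suite verifies ~95%
  nominal behaviour at 8-patient scale.
* **Patient fixed-effects slope** at the fraction level: the within
  estimator (demeaning absorbs patient intercepts) with a linear
  fraction-index covariate, patient-clustered robust SEs with CR1
  small-sample scaling and t(G-1) reference.  The estimator is tested to
  be algebraically identical to dummy-variable OLS.

Multiplicity: the five endpoints form one family; Spearman and OLS
p-values are adjusted by Benjamini-Hochberg *as two separate five-test
families* by default, because the published table aligns a single FDR
column with the OLS p-values; a pooled ten-test mode is provided since the
original family convention is ambiguous.  Fixed-effects p-values are
confirmatory and never adjusted.  All resampling takes explicit seeds and
restores the caller's RNG state.

## NTCP

Acute-bowel-toxicity risk is the logistic model
`NTCP = 1 / (1 + (V50 / V45)^k)` on whole-bowel V45 in cc, with published
parameters V50 = 130 cc and k = 1.1; V45 = 0 maps to 0 by continuous
limit, and the model is monotone with NTCP(V50) = 0.5 exactly.  Exploratory
triage bands cut V45 at 300 and 500 cc, with both edges assigned to the
middle band.  `compare_planned_accumulated()` computes per-patient NTCP
from planned and accumulated DVHs separately and reports per-stratum
means +/- SD with two-sided paired t-tests; zero-variance differences and
single-patient strata are flagged `degenerate` instead of being given a
meaningless p-value.  Synthetic toxicity grades, where needed for
table shape, are band memberships with optional label noise and carry no
clinical meaning.  Model fitting (V50, k) from data is out of scope.

## Problem sizes and numerical choices

The test suite runs the full pipeline at reduced scale by design: identity
and determinism tests use a half-scale pelvis on 32 x 32 x 24 grids,
cap/realisation properties a 0.62-scale pelvis on 48 x 48 x 36 grids, and
the realism checks (PTV volume, realisation accuracy) the default
64 x 64 x 48 grid.  The coverage study uses 500 replicates of an
8-patient x 25-fraction panel.  These sizes were chosen so the whole suite
completes in minutes on a single core while still exercising every module
at full fidelity; nothing in the methods depends on grid size beyond the
quantisation effects discussed above.

Other numerical conventions: voxel indices are 0-based with
`world = origin + index x spacing` (mm) and half-open voxel sets; ray
marching uses midpoint sampling; the DVF is stored as a 4-D array of mm
displacements on planning geometry; secant solvers on voxelised volumes
stop at the best evaluated candidate (an exact root generally does not
exist on a lattice).

## Known limitations

* The dose engine is a physics sketch: no scatter kernel, no couch, no
  fluence optimisation.  Absolute dosimetric accuracy is out of scope; only
  directionally correct density sensitivity is claimed or tested.
* The phantom has no CT texture, breathing, or intra-fraction motion, and
  no stomach (the exclusion rule is still enforced structurally).  Passing
  tests demonstrate correctness of the analysis chain under controlled
  motion, not clinical performance on real CBCT.
* The registration is ground truth by construction; QA gates are exercised
  by perturbation, not by a real registration failure mode.
* Cohort-scale clinical results (published medians, correlations, slopes)
  depend on patient images that are not available; the package's
  property-based substitutes (identity-course null, parameter recovery,
  selective gas effect) are the appropriate verifiable surrogates.
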