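---
title: "Lean body mass from limited-coverage CT and its impact on PERCIST classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lean body mass from limited-coverage CT and its impact on PERCIST classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbmct)
library(tibble)
```

## The problem

PET response assessment under PERCIST 1.0 is built on SUL — the
standardized uptake value normalised by lean body mass (LBM) rather than
total body weight. Clinical PET systems estimate LBM with the James
predictive equation from sex, weight and height alone. That equation is
population-derived and can be badly wrong for an individual, particularly
in extreme body habitus, and any error propagates multiplicatively into
every SUL measurement.

A routine PET/CT examination, however, already contains a direct (if
incomplete) measurement of body composition: the limited-coverage (LC) CT,
typically covering the thorax to the ischium. `lbmct` implements a
patient-specific alternative: segment fat on the LC CT by Hounsfield-unit
(HU) window, convert the LC fat volume to an estimate of whole-body fat
mass through a linear calibration, and subtract from body weight to obtain
LBM. It then quantifies the downstream clinical question: when the same
lesion SUL measurements are re-normalised with the CT-derived LBM, how
often does the PERCIST response class change, and for whom?

## The model

**Fat volumetry.** Fat voxels on CT are those with
$-190 \le \mathrm{HU} \le -30$ (both bounds inclusive — the conventional
adipose window). Fat volume is the voxel count times the voxel volume; the
binary mask counts partial-volume voxels whole. Volume converts to mass
with the adipose density $\rho = 0.923$ kg/L.

**LBM estimators.** Three estimators share one interface:

* James predictive equation:
  $\mathrm{LBM} = 1.10\,W - 120\,(W/H)^2$ for males,
  $\mathrm{LBM} = 1.07\,W - 148\,(W/H)^2$ for females
  ($W$ kg, $H$ cm).
* Limited coverage: $\mathrm{LBM} = W - (\alpha + \beta\,\mathrm{FV_{LC}})$
  with $\mathrm{FV_{LC}}$ in litres. The packaged default coefficients are
  $\alpha = 2.892$ kg, $\beta = 1.3337$ kg/L, from a 199-patient
  development cohort; `fit_fat_model()` refits them on any cohort by
  ordinary least squares. The litre convention matters: only with
  $\mathrm{FV_{LC}}$ in litres are the coefficients dimensionally
  consistent with the development-cohort means
  (mean $\mathrm{FV_{LC}} = 11.084$ L predicts
  `r round(predict(default_fat_model(), 11.08401), 2)` kg of fat,
  matching the reported cohort mean of 17.71 kg to coefficient rounding).
* Whole-body reference: $\mathrm{LBM} = W - \mathrm{FM_{WB}}$ with fat
  mass measured on whole-body CT; this is the reference standard the other
  two are judged against (paired t tests and Bland–Altman limits of
  agreement, `paired_comparison()` and `bland_altman()`).

Implausible estimates (non-positive, or above body weight) are returned
flagged rather than clamped: silently repairing them would hide exactly
the pathology that motivates CT-derived LBM.

**PERCIST.** Because SUL is proportional to the LBM used, a SUL peak
computed under one LBM algorithm converts to another by a pure ratio
(`rescale_sul_peak()`); the PET data never need re-measuring. Response is
classified from the percent change of the target-lesion SUL peak between
baseline and follow-up: PMR at $\le -30\%$, PMD at $\ge +30\%$, SMD
otherwise, thresholds inclusive, with a minimal absolute change gate
(default 0.8 SUL in `classify_response()`, taken from PERCIST 1.0). The
supporting measurement chain is implemented too: iterative adaptive lesion
segmentation (threshold update
$T \leftarrow w\,\mathrm{SUV_{max}} + (1-w)\,\mathrm{SUV_{mean}}$,
default $w = 0.5$, 26-connectivity to the seed maximum), the 12-mm
(≈1 cm³) SUL-peak sphere, the 3-cm liver background ROI, the
measurability rules ($\ge 1.5\cdot$liver mean $+ 2$ SD, read as the
standard PERCIST parse; the stricter $1.5(\mu + 2\sigma)$ parse is a
flag), and the hottest-lesion target rule with lexicographic tie-break.

**Concordance.** Paired classifications from the two algorithms are
summarised as a 3×3 contingency table, unweighted Cohen's κ (linear
weights behind a flag), the signed-rank test on the ordinal classes
(zero-difference policy recorded in the output; discard + tie-corrected
normal approximation by default, exact enumeration up to n = 25), and the
threshold-band analysis: counting patients whose percent change lies
within ±5 or ±10 points of the ±30% threshold and the discordant fraction
among them.

## Why discordance concentrates near the threshold

Let $g = 1 + \Delta_{PE}/100$ be the SUL-peak ratio under the James
equation and $r$ the ratio of LBM changes,
$r = \frac{\mathrm{LBM_{LC,f}}/\mathrm{LBM_{LC,b}}}{\mathrm{LBM_{PE,f}}/\mathrm{LBM_{PE,b}}}$.
Then the LC-based percent change is $100(gr - 1)$. If LBM is unchanged at
both timepoints, $r = 1$ and the two classifications agree for every
patient. When LBM changes, $r$ deviates from 1 by at most a few percent,
so the two percent changes can straddle the ±30% cut only if the first
one already sits near it. That is the core mechanism the package
simulates and tests.

## The synthetic generators

No patient data ship with the package; every test input is generated with
known ground truth.

* `make_ct_phantom()` — a nested-ellipsoid body (outer fat shell over a
  lean core, default semi-axes 100/80/200 mm over 80/60/180 mm) in air,
  with an optional detached couch slab. Voxel membership is
  center-in-shape, so an exact voxel-count fat volume exists alongside the
  analytic $\tfrac{4}{3}\pi(a_1a_2a_3 - b_1b_2b_3)$. Tissue HU noise is
  Gaussian (fat $-100 \pm 20$ truncated to the segmentation window, lean
  $40 \pm 10$, air $-1000$), so intensity noise never changes fat
  membership and geometry error is testable in isolation.
* `make_pet_phantom()` — a uniform spherical lesion in a uniform
  background plus a designated liver region, giving closed-form SUL peak
  and background statistics.
* `make_cohort()` — subjects with the development-cohort demographic
  profile (n = 199; 106/93 male/female; male weight
  $63.5 \pm 15.1$ kg, height $166.6 \pm 6.7$ cm; female $56.2 \pm 9.2$ kg,
  $156.3 \pm 5.9$ cm), lognormal $\mathrm{FV_{LC}}$ with mean 11.084 L and
  SD 5.2 L (the SD chosen as roughly one sixth of the observed cohort
  range), and $\mathrm{FM_{WB}} = \alpha + \beta\,\mathrm{FV_{LC}} +
  \mathcal N(0, 1.5^2)$ kg. The 1.5-kg noise puts the sample Pearson r
  near the reported 0.977. Fat mass is constrained to $(0, W)$ by
  bounded redraws.
* `make_percist_cohort()` — paired-timepoint cohorts (default n = 241)
  whose LBM change between timepoints follows a categorical mixture of the
  three observed discordance mechanisms: concordant decrease
  (PE $-7.2 \pm 2.2\%$ vs LC $-2.8 \pm 1.8\%$), concordant increase
  ($+5.7 \pm 1.5\%$ vs $+1.8 \pm 1.7\%$), and divergent weight gain with
  muscle loss (PE $+1.8 \pm 1.0\%$ vs LC $-4.8 \pm 1.9\%$), plus a
  no-change class. Mixture weights default to
  (0.5, 0.3, 0.1, 0.1) — the three active mechanisms in roughly the
  16:5:6 proportion seen among discordant patients, applied to a cohort
  half of which shows no appreciable LBM change. True tumour percent
  changes are drawn from the two observed response groups
  ($-39.78 \pm 18.52\%$ decreasing, $+34.03 \pm 19.18\%$ increasing, 60%
  decreasing).

What the generators do **not** emulate: real anatomy (arms, organs,
couch curvature), scanner physics and reconstruction noise, partial-volume
effects at fat boundaries, respiratory misalignment between CT and PET,
or any joint distribution between tumour response and body-composition
change (the mechanism mixture is independent of the true tumour change,
as nothing in the observed summaries constrains that dependence).
Passing tests therefore validate the arithmetic, geometry and statistical
machinery — not the clinical accuracy of the calibration on real
patients, which requires patient data the package does not ship.

## Numerical choices

* **Truncation at 3 SD** for all mechanism and tissue draws. This keeps
  the LBM-ratio factor $r$ inside hard algebraic bounds, which makes the
  "discordance only near the threshold" property exactly testable
  (patients outside the reachable band must be concordant, not merely
  usually so).
* **Phantom alignment.** The phantom ellipsoid center is offset from the
  voxel grid by a fixed sub-voxel fraction (0.31, 0.47, 0.61 voxels).
  A grid-symmetric ellipsoid produces accidentally cancelling
  discretization error at particular resolutions; the generic alignment
  restores the typical first-order error decay that the convergence test
  (4 → 2 → 1 mm) is meant to demonstrate.
* **Simulator classification gate.** `classify_percist_cohort()` defaults
  the minimal-absolute-change gate to 0 while `classify_response()` keeps
  the clinical 0.8 SUL. The gate acts on the SUL scale itself and does
  not cancel under LBM rescaling, so with the gate on, two algorithms can
  disagree even with identical percent changes — noise unrelated to the
  LBM-change mechanism the simulation isolates, and incompatible with the
  exact invariant "unchanged LBM implies identical classifications".
  The clinical gate can be switched back on per call.
* **Adaptive segmentation** stops when the threshold moves less than
  `tol` (default 1e-6 SUL); on a finite image the mask sequence then
  stabilises to an exact fixpoint of the update rule, which the tests
  verify against exhaustive threshold enumeration. Non-convergence within
  `max_iter` returns the last mask with a warning rather than failing.
* **Degenerate inputs** are errors with typed conditions
  (`lbmct_domain_error`, `lbmct_geometry_error`, ...): zero-variance
  paired differences, empty masks, spheres that do not fit the volume,
  fat mass at or above body weight.
* **Background SD** defaults to the sample convention (n − 1), matching
  clinical software; population SD is available via `sd_type`.
* **Wilcoxon policy.** The reported p-value depends on the
  zero-difference policy and approximation; both are always recorded in
  the output. For a 241-patient table with 27 discordant pairs the
  discard + tie-corrected normal approximation gives z ≈ −0.96,
  p ≈ 0.34; published software conventions vary, and no single
  convention reproduces every reported value, so the package reports its
  policy rather than matching any one program.
* **Test problem sizes.** The test suite uses phantoms at 4–2 mm spacing
  with the 1-mm phantom exercised in the acceptance checks, 100-seed
  confidence-interval coverage for the regression recovery, and a
   Monte-Carlo ensemble of simulated cohorts for the discordance-location
  property; these sizes give stable pass/fail behaviour at interactive
  runtimes.

## Design decisions that were genuinely open

* **Pooled regression.** The fat-model regression pools sexes (a single
  published equation exists); fitting per subgroup is possible by
  filtering the cohort table before `fit_fat_model()`.
* **Body mask off by default.** The described volumetry method is a bare
  HU window; `body_mask()` (largest 26-connected component above
  −500 HU, morphologically closed) is offered for real scans where couch
  and bag voxels would otherwise count, and its use is recorded in the
  result's provenance columns.
* **LC landmarks are user-supplied slice indices.** The thorax-top and
  ischium landmarks have no algorithmic definition here; automatic
  anatomical landmarking is out of scope.
* **CMR is not emitted.** The three-class output (PMD/SMD/PMR) matches
  the intended application to cohorts with persisting FDG-avid disease; a
  complete-response class would require background-relative logic that
  the package's inputs do not carry.
* **DICOM reading is deliberately minimal**: uncompressed little-endian,
  16-bit grayscale, single series per directory, slices ordered by
  physical position with a 1% spacing-consistency check. NIfTI (with a
  JSON sidecar for exact geometry and modality) is the native format.

## Limitations

The default calibration (α = 2.892, β = 1.3337) was developed on a single
scanner and cohort with few obese subjects; applying it elsewhere without
refitting assumes the FV→FM relationship transfers. The discordance
simulation reproduces the observed mechanism *magnitudes*, not their
joint distribution with tumour response. And the package takes lesion SUL
peaks as given (or from phantoms); it does not detect lesions.
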