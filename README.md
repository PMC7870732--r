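# lbmct

Patient-specific lean body mass (LBM) from the limited-coverage CT of a
routine PET/CT examination, and the downstream question it exists to
answer: **does the choice of LBM algorithm change PERCIST 1.0
treatment-response classifications?**

PERCIST assesses tumour response from the percent change of SUL — SUV
normalised by LBM — between baseline and follow-up PET, with a ±30%
threshold. Scanners estimate LBM with the James predictive equation
(sex, weight, height), which can be substantially wrong for an
individual; every SUL inherits that error. `lbmct` implements the
CT-derived alternative and the concordance analysis between the two:

* **Fat volumetry** on CT: adipose voxels are those with
  −190 ≤ HU ≤ −30; fat volume × density 0.923 kg/L gives fat mass.
  Includes an optional body mask (largest connected component +
  morphological closing) to exclude couch artefacts.
* **LBM estimators**:
  James (`LBM = 1.10 W − 120 (W/H)²` male, `1.07 W − 148 (W/H)²`
  female); limited coverage
  (`LBM = W − (α + β·FV_LC)`, FV_LC in litres, defaults
  α = 2.892 kg, β = 1.3337 kg/L, refittable by OLS with
  `fit_fat_model()`); and the whole-body CT reference `W − FM_WB`.
* **PERCIST machinery**: SUV→SUL conversion, exact SUL re-normalisation
  between LBM algorithms (a pure LBM ratio), iterative adaptive lesion
  segmentation, the 1-cm³ SUL-peak sphere, liver/blood-pool
  measurability rules, hottest-lesion target selection, and three-class
  response classification (PMR/SMD/PMD, inclusive ±30% with a minimal
  absolute-change gate).
* **Concordance statistics**: 3×3 contingency tables, Cohen's κ,
  signed-rank tests on ordinal classes with explicit zero-difference
  policy, paired t, Bland–Altman limits of agreement, and the
  threshold-band analysis locating discordance relative to ±30%.
* **Synthetic generators** with known ground truth: nested-ellipsoid CT
  phantoms (analytic fat volume), PET lesion phantoms, regression
  cohorts, and paired-timepoint PERCIST cohorts driven by the observed
  LBM-change mechanisms.

Volumes are read/written as NIfTI-1 (with a JSON sidecar for exact
geometry) or read from uncompressed DICOM series; tabular interfaces are
data-frame-in, tibble-out. A thin command-line wrapper ships in
`inst/cli/lbmct`.

## Worked example

Fit the fat-volume calibration on a synthetic development cohort, apply
it to a subject, then simulate a paired-timepoint cohort and measure how
the two LBM algorithms disagree:

```r
library(lbmct)

cohort <- make_cohort(n = 199, seed = 7)   # known truth: 2.892 + 1.3337 FV
m <- fit_fat_model(cohort)
m
#> <fat_model> FM_WB = 2.778 + 1.338 * FV_LC [kg; FV_LC in L]
#>   Pearson r = 0.9769, n = 199
#>   provenance: fitted from cohort

lbm_lc(weight_kg = 63, fv_lc_l = 11.5, model = m)
#> # A tibble: 1 × 6
#>   method           weight_kg fv_lc_l fm_wb_pred_kg lbm_kg flagged
#> 1 limited_coverage        63    11.5          18.2   44.8 FALSE
```

The fitted line recovers the generating coefficients (α within its
standard error, r ≈ 0.977), and the subject's LBM is body weight minus
the predicted whole-body fat mass — 18.2 kg of fat, 44.8 kg lean.

```r
pc  <- classify_percist_cohort(make_percist_cohort(n = 241, seed = 7))
tab <- build_contingency(pc)
tab
#> <contingency3> rows: PE, columns: LC, n = 241
#>     PMD SMD PMR
#> PMD  63   4   0
#> SMD   1  70   3
#> PMR   0   2  98
concordance_report(tab)[, 1:6]
#> # A tibble: 1 × 6
#>       n kappa observed_agreement expected_agreement discordant_n discordant_pct
#> 1   241 0.937              0.959              0.345           10           4.15

threshold_band_analysis(pc)
#> # A tibble: 3 × 5
#>   band       half_width n_in_band n_discordant discordant_fraction
#> 1 within_5            5        39            8               20.5
#> 2 within_10          10        84           10               11.9
#> 3 shell_5_10         10        45            2                4.44
```

Ten of 241 simulated patients change response class purely because the
two algorithms disagree about how LBM evolved between scans — and all of
them sit within 10 percentage points of the ±30% threshold, the
signature of the re-normalisation mechanism (the LBM ratio shifts each
percent change by only a few points, so only near-threshold patients can
cross it). Discordance is never an artefact of the PET measurements
themselves: `rescale_sul_peak()` converts SUL exactly between
algorithms.

See the vignette (`vignettes/lbm-from-limited-coverage-ct.Rmd`) for the
model details, generator assumptions and numerical choices.

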