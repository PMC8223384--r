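# aortacalc

Semi-automated quantification of descending thoracic aortic calcification
from paired CT and radial-VIBE CMR volumes, with the full method-agreement
analysis needed to compare the two modalities — plus a digital phantom and
cohort simulator so the whole pipeline runs and validates without patient
data.

## What it computes

**On CT** (calibrated Hounsfield units): after a per-slice circular median
filter (3 mm radius, suppressing salt-and-pepper noise), a voxel inside the
aortic ROI is calcified iff its attenuation is ≥ 130 HU. Calcium burden is
the volume score

```
Volume (mm³) = Σ over slices ( lesion area in mm² × slice thickness in mm )
```

and, for coronary-style reporting, the Agatston score Σ lesions (area ×
density weight), the weight 1–4 set by the lesion's maximum HU
(130–199 / 200–299 / 300–399 / ≥ 400).

**On radial-VIBE CMR** (uncalibrated intensities; calcium is hypointense):
a per-slice adaptive threshold. With mean m and sample SD s of the ROI
intensities of each slice, a voxel is calcified iff its intensity ≤
m − k·s, default k = 2.5. The same volume score is applied. No median
filter is used on MR — it removes genuine small calcium along with noise.

**Agreement analysis** between the two volume measurements: Spearman ρ with
Fisher-z 95% CI; OLS with standardized-residual (|r| ≥ 3) outlier screening
and a sensitivity re-fit; Bland–Altman mean bias and crude limits of
agreement `bias ± 1.96·SD(d)`, plus a regression-based version for
proportional bias (bias modelled as c₀ + c₁·mean, LOA = bias line ±
1.96 × residual SD); single-rating two-way mixed ICC in consistency and
absolute-agreement variants with McGraw–Wong confidence intervals; weighted
Cohen's κ for paired ordinal quality ratings; Shapiro–Wilk and
Kolmogorov–Smirnov normality checks.

**Synthetic data**: `make_paired_phantom()` renders a straight-tube aorta
with wedge-shaped wall lesions into a CT volume (Gaussian noise +
salt-and-pepper corruption) and an MR volume (Rician noise, optional
within-ROI degradation), with exact voxel-level ground truth.
`simulate_cohort()` draws per-subject paired volumes with zero-inflated
log-normal CT, a linear CT→MR link with positive intercept (default
192.4 + 0.31·CT), an Agatston score rank-linked to CT, and two observers'
Likert ratings.

## Worked example

```r
library(aortacalc)

p   <- make_paired_phantom(phantom_spec(lesions = demo_lesions()))
seg <- select_segment(p$ct, landmark = 4, length_mm = 90)
#> <segment_selection> slices [4, 34) (30 slices, increasing), 90.0 mm requested, 90.0 mm realised

ct <- segment_calcium_ct(median_filter_ct(p$ct, 3), p$roi, seg, ct_config())
mr <- segment_calcium_mr(p$mr, p$roi, seg, mr_config(k = 2.5))
ct; mr; p$truth$total_volume_mm3
#> <calcification_result> CT: total volume 1209.60 mm^3 over 30 slices (280 voxels flagged)
#> <calcification_result> MR: total volume 1481.76 mm^3 over 30 slices (343 voxels flagged)
#> [1] 1481.76
```

The noiseless MR route recovers the 1481.76 mm³ ground truth exactly; the
CT route recovers it exactly with the median filter off, and loses only
lesion-boundary voxels (here 272 mm³ across three lesions' rims) with the
filter on — the filter's corner-rounding is the documented cost of its
noise robustness.

```r
report <- build_report(simulate_cohort(cohort_sim_params(seed = 3)))
report
#> <agreement_report> n = 96 (0 dropped)
#>   Spearman rho = 0.386 [0.202, 0.545], p = 8.48e-05
#>   OLS: y = 195.90 +0.355 x (R^2 = 0.462), 0 outlier(s)
#>   Bias model: 248.40 -0.733 * mean, LOA offset +/- 312.39
#> ICC (consistency, single-rating, 2-way mixed): 0.558 [0.403, 0.682]
#> ICC (absolute agreement, single-rating, 2-way mixed): 0.502 [0.269, 0.665]
#>   Weighted kappa (linear) = 0.845 [0.756, 0.933]
```

Read: at study scale (n = 96) the two modalities correlate moderately; the
positive OLS intercept is the MR over-detection at zero CT calcium; the
negative bias-model slope is the proportional bias (MR reads higher than CT
at low burden, lower at high burden); the ICC pair quantifies moderate
consistency; κ reflects strong inter-observer agreement on image quality.

`run_pipeline(run_config(out_dir = "out", seed = 1))` chains all of the
above and writes `ct.nii.gz`, `mr.nii.gz`, `roi.nii.gz`, `truth.json`,
`ct_result.json`, `mr_result.json`, `cohort.csv` and `report.json`;
repeated runs with the same seed are byte-identical.

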