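---
title: "Quantifying thoracic aortic calcification from paired CT and radial-VIBE CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thoracic aortic calcification from paired CT and radial-VIBE CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortacalc)
```

## The measurement problem

Vascular calcification predicts cardiovascular events, and CT is the
reference modality for measuring it: Hounsfield units are calibrated (water
= 0 HU), so a fixed attenuation threshold identifies calcium reproducibly
across patients and scanners. MRI has no such calibration — the signal
intensity of the same tissue varies with coil, sequence and patient — yet a
proton-density-weighted radial-VIBE acquisition shows calcium as
well-defined hypointense (dark) regions, and avoids ionising radiation,
which matters for serial imaging in young or research populations such as
patients with end-stage renal disease.

`aortacalc` implements both quantification routes for the descending
thoracic aorta and the statistical machinery needed to compare them as
measurement methods. Because the underlying patient scans of this study
design are not public, the package also provides a digital phantom and a
cohort simulator with known ground truth, so every step of the pipeline is
testable end to end.

## The analysis segment

Both modalities are analysed over the same anatomy: a 9 cm segment of the
descending thoracic aorta, starting at a landmark slice (the top of the
vertebra closest to the diaphragmatic surface of the heart) and progressing
superiorly. `select_segment()` converts the physical length into
`round(length / slice spacing)` axial slices (ties round away from zero; at
the 3 mm reconstructed slice spacing used throughout, 90 mm is exactly 30
slices). Slice indices are 0-based and ranges half-open, so segments
compose without off-by-one ambiguity; the direction toward superior must be
stated explicitly because axis orientation varies between files. The
segment length is measured along the slice axis; with the aorta modelled as
a straight tube parallel to that axis the distinction from a centreline
measurement vanishes, and for mildly curved real anatomy it is a
second-order effect.

The per-slice region of interest (the aortic wall and lumen) is supplied as
a binary mask aligned to the volume — in the phantom it is generated; for
real data it would be drawn manually, a step that is out of scope here.

## CT quantification

CT processing has three stages, deliberately separable:

1. **Median filtering** (`median_filter_ct()`): a 2-D, per-slice median
   over a circular neighbourhood of 3 mm physical radius (a pixel belongs
   to the kernel if its centre lies within the radius; borders replicate
   the edge). The filter suppresses salt-and-pepper noise while preserving
   step edges. Radius 0 disables it, making "what would the result be
   without the filter" a configuration change rather than a code change.
2. **Thresholding** (`segment_calcium_ct()`): a voxel is calcified iff it
   is inside the ROI, inside the segment, and its attenuation is **at or
   above 130 HU** — the conventional calcium threshold, roughly two
   standard deviations above unenhanced blood. The comparison is inclusive.
3. **Scoring**: the volume score is `sum(area per slice x slice
   thickness)` (`compute_volume()`), with no minimum lesion size — any
   flagged voxel contributes. The Agatston score (`agatston_score()`)
   groups flagged voxels into in-plane connected lesions (4-connectivity
   by default, configurable to 8), drops lesions under 1 mm², and scores
   each as area times a density weight from the lesion's maximum
   attenuation: 130–199 HU → 1, 200–299 → 2, 300–399 → 3, ≥ 400 → 4.

The slice interval is assumed equal to the slice thickness (both 3 mm in
the intended reconstruction); the volume container carries a single
per-axis spacing, so overlapping or gapped reconstructions cannot be
mis-volumed silently.

A note on the filter: a median filter is idempotent on straight step edges
(they are root signals of the disc kernel), but it rounds sharp convex
corners, so small or thin lesions lose boundary voxels. The tests therefore
require exact ground-truth recovery only with the filter off, and recovery
within a one-voxel boundary shell with it on.

## Radial-VIBE quantification

With no absolute intensity scale, the MR threshold adapts per slice
(`segment_calcium_mr()`): a voxel is calcified iff it lies in the ROI and
its intensity is at or below `mean - k * SD` of that slice's ROI
intensities, with `k = 2.5` by default. The neighbouring values bracket the
useful range: `k = 2` fails to separate calcification from noise and `k =
3` excludes visually obvious calcium, so `k` is exposed as a parameter
(including on the command line) rather than hard-coded.

Design choices that matter:

- **Single-pass statistics.** The slice mean and SD are computed over *all*
  ROI voxels, calcified ones included, with the sample (n − 1) denominator.
  This has a quantifiable consequence: a lesion occupying fraction *f* of a
  slice's ROI at contrast Δ below the remaining tissue inflates the SD by
  roughly `sqrt(f(1-f)) * Δ`, and detection of the lesion itself requires
  approximately `f <= 1/(1 + k^2)` (≈ 0.14 at k = 2.5). Very large lesions
  therefore *raise* their own threshold out of reach — a real failure mode
  of this class of algorithm that the package reproduces rather than hides.
- **Degenerate slices.** If the ROI is exactly uniform (SD = 0) the literal
  rule `v <= mean` would flag every voxel; such slices are treated as
  containing no detectable calcification (a documented policy flag).
  Slices with fewer than two ROI voxels cannot yield an SD and contribute
  zero area, flagged in the per-slice output. If *every* segment slice
  lacks valid statistics the function errors, because "no usable
  statistics" must not masquerade as "zero calcification".
- **No median filtering of MR.** Filtering was evaluated for this approach
  and rejected — it removes genuine small calcium along with the noise —
  so the package does not offer it for MR even as an option.
- **Affine invariance.** The threshold transforms exactly as the data
  under `v -> a*v + b` (a > 0), so detection is invariant to linear
  intensity rescaling — the property that makes an adaptive rule the right
  choice for uncalibrated MR in the first place. This is asserted as a
  property test.

## The digital phantom

`make_paired_phantom()` renders a `phantom_spec()`: a straight
blood-filled tube (lumen radius 9.6 mm, wall 4.8 mm) aligned with the
slice axis on a 64 × 64 × 40 grid at 1.2 × 1.2 × 3.0 mm spacing — in-plane
acquisition resolution with 3 mm reconstructed slices. Calcified lesions
are wedges of the wall annulus with per-lesion slice range, angular
extent, radial depth, CT attenuation and MR signal. Ground truth is
analytic: per-lesion voxel masks and volumes equal to voxel count times
voxel volume, exactly.

Noise models follow the modalities: additive Gaussian noise then
salt-and-pepper corruption (the explicit motivation for the CT median
filter) on CT; Rician noise — the magnitude of a complex Gaussian
perturbation — on MR. A degraded-quality factor multiplies the within-ROI
MR noise scale to emulate scans in which in-aorta noise inflates the
adaptive threshold until detection fails; driving that factor up a ladder
reproduces the monotone collapse of Dice overlap to zero that motivates
subjective quality review before algorithmic quantification.

Two intentional simplifications: the lumen and wall are given slightly
different MR signal levels (380 and 420 arbitrary units) so that even a
noiseless ROI has a nonzero SD and the adaptive threshold is well defined;
and the aorta is straight, since every operator works per slice and
curvature would only complicate the ground truth. The phantom does not
simulate k-space acquisition, motion, partial-volume averaging at lesion
boundaries, susceptibility artefacts, or CT blooming — so exact-recovery
tests demonstrate correctness of the *operators*, not clinical performance
on real scans.

All randomness flows from one integer seed per generator call; identical
specs give byte-identical volumes.

## The cohort simulator

`simulate_cohort()` generates per-subject paired measurements with the
statistical structure the agreement analysis is designed to detect:

- CT volume is zero-inflated (default zero fraction 0.417) with a
  log-normal positive part (meanlog 4.47, sdlog 1.93). These defaults were
  solved from an overall median of 11 mm³ given the zero fraction and an
  expected maximum near 5000 mm³ at n = 96, the scale of severe aortic
  calcification in end-stage renal disease.
- MR volume is `192.4 + 0.31 * CT` plus Gaussian noise (floor SD 100 mm³,
  calibrated to an apparent-MR-volume spread of roughly 65–480 mm³ among
  zero-CT subjects), truncated at zero. The positive intercept means every
  zero-CT subject still shows apparent MR signal — the over-detection
  pattern at low calcium burden — while the slope below 1 produces
  under-detection at high burden, i.e. proportional bias.
- A coronary Agatston score with positive rank-dependence on CT volume,
  and two observers' 5-point quality ratings with ~80% concordance around
  a mean near 4.6.

Two numerical caveats are documented rather than hidden. First, truncation
at zero lifts the expected MR volume of zero-CT subjects slightly above the
intercept (by `E[max(0, N(a, s))] - a`, about 1.1 mm³ at the defaults), so
ordinary least squares recovers the generator intercept within its nominal
3-standard-error band at n = 10⁴ but not asymptotically; the recovery check
is run at 10⁴. Second, a heteroscedasticity coefficient (noise SD growing
with CT volume) is available to mimic the growth of between-method spread
with magnitude seen in real data, but it defaults to 0: combined with the
heavy-tailed CT marginal it invalidates classical OLS standard errors, and
link recoverability by the same OLS the analysis uses is the property the
default generator guarantees.

## Agreement statistics

`build_report()` assembles the full method-comparison analysis from
components that are each exported and individually tested:

- **Spearman ρ** as the Pearson correlation of mid-ranks, with a Fisher-z
  95% CI (SE `1/sqrt(n-3)`) and asymptotic two-sided p. Rank-based
  correlation is displayed because calcium volumes are heavily skewed;
  normality tests (Shapiro-Wilk, Kolmogorov-Smirnov) are computed as
  advisory context.
- **OLS with outlier screening**: standardized residuals are raw residuals
  over the residual standard error (n − 2); subjects at |r| ≥ 3 are
  flagged and a sensitivity re-fit excluding them is part of the output.
  The leverage-adjusted (studentized) variant is available since software
  packages differ in what they call a "standard residual".
- **Bland-Altman**: mean bias (comparator minus reference) and crude 95%
  limits of agreement `bias ± 1.96 SD(d)`; because proportional bias
  violates the constant-bias assumption, the bias is additionally modelled
  by regressing differences on pair means, with limits of agreement as the
  bias line ± 1.96 times the residual SD (n − 2). When the fitted slope is
  exactly zero the two analyses coincide up to the n − 1 vs n − 2
  denominator — an identity the tests assert.
- **ICC**, single-rating, two-way mixed, in both the consistency and the
  absolute-agreement variants from the same mean squares, with
  McGraw-Wong F-based confidence intervals (Satterthwaite degrees of
  freedom for the absolute variant). Variant and model tags travel with
  every estimate because ICC naming is notoriously ambiguous.
- **Weighted Cohen's κ** for the paired ordinal quality ratings, linear
  disagreement weights `|i-j|/(R-1)` by default (quadratic available, and
  the choice is recorded in the report), with the Fleiss-Cohen-Everitt
  large-sample CI.

No ICC or kappa implementation was taken from a library; both are authored
from the ANOVA mean squares and the weighted contingency table directly,
and the test suite validates every statistic against independent
brute-force recomputations (naive loops over ranks, cells and sums of
squares) to 10⁻¹⁰ on batches of random tables, plus hand-worked fixtures
with exact rational answers.

Subjects with any missing required value are dropped listwise with a
logged count; the kappa block is simply omitted (with a notice) when no
rating columns are present.

## Reproducibility and problem sizes

`run_pipeline()` chains phantom → CT and MR quantification → cohort
simulation → agreement report, writing NIfTI volumes, JSON results and the
cohort CSV to one directory; a single global seed derives per-stage
sub-seeds, and repeated runs are byte-identical. The test suite exercises
the default 64 × 64 × 40 phantom, cohorts of 96 (the study-scale default)
and simulator-fidelity checks at 10⁴–10⁵ subjects; these sizes keep the
whole suite under a minute on a laptop while leaving every statistical
tolerance at its analytic value (3 Monte-Carlo or regression SEs, 10⁻¹⁰
for oracle equivalence).

## Known limitations

- The phantom's MR contrast levels are free parameters: no tissue-class
  intensity statistics exist for this sequence in the source setting, so
  exact MR recovery results validate the algorithm, not scanner realism.
- Manual ROI delineation — the dominant practical difficulty on real
  radial-VIBE images, where the wall boundary is visually obscured — is
  out of scope; the phantom supplies perfect masks.
- The per-slice adaptive threshold inherits the large-lesion failure mode
  described above; iterative re-estimation excluding flagged voxels would
  change the algorithm under study and is deliberately not implemented.
- Spearman p-values and CIs are asymptotic; at very small n a permutation
  approach would be preferable.
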