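Package: aortacalc
Title: Semi-Automated Quantification of Thoracic Aortic Calcification
    from CT and Radial-VIBE CMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying descending thoracic aortic calcification
    from paired computed tomography (CT) and proton-density-weighted
    radial-VIBE cardiovascular magnetic resonance (CMR) volumes. Implements
    fixed 130-HU thresholding with circular median filtering and Agatston
    scoring on CT, a per-slice adaptive (mean minus k standard deviations)
    intensity threshold on CMR, the summed area-times-slice-thickness
    calcium volume score, and a full method-agreement analysis (Spearman
    correlation with Fisher-z intervals, ordinary least squares with
    standardized-residual outlier screening, crude and regression-based
    Bland-Altman limits of agreement, two-way mixed single-measure
    intraclass correlation, weighted Cohen's kappa, and normality checks).
    Includes a digital phantom generator producing paired CT/CMR volumes
    with known calcification ground truth, and a cohort simulator with
    zero-inflated calcium volumes and proportional between-modality bias,
    so the whole pipeline can be exercised and validated without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
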