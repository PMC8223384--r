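#' Radial-VIBE quantification configuration
#'
#' MR signal intensity has no absolute calibration, so calcification (which
#' is hypointense on proton-density-weighted radial-VIBE images) is detected
#' relative to each slice's own aortic ROI statistics: a voxel counts as
#' calcified when its intensity is at least `k` standard deviations below the
#' ROI mean of that slice.
#'
#' @param k SD multiplier (dimensionless, > 0). Default 2.5: 2 fails to
#'   separate calcification from noise while 3 excludes obvious
#'   calcification.
#' @param min_voxels Minimum ROI voxel count for a slice to yield valid
#'   statistics (default 2; the sample SD needs at least two values).
#' @param zero_sd_detects Policy for slices whose ROI intensities are exactly
#'   uniform (SD = 0). The literal rule `v <= mean - k*0` would flag every
#'   ROI voxel; the default `FALSE` treats such slices as containing no
#'   detectable calcification.
#'
#' @return An object of class `mr_config`.
#' @export
mr_config <- function(k = 2.5, min_voxels = 2L, zero_sd_detects = FALSE) {
  if (!is.finite(k) || k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (min_voxels < 2L) stop("`min_voxels` must be >= 2", call. = FALSE)
  structure(list(k = k, min_voxels = as.integer(min_voxels),
                 zero_sd_detects = isTRUE(zero_sd_detects)),
            class = "mr_config")
}

#' Per-slice adaptive threshold
#'
#' Threshold for one slice: `mean - k * SD` of the ROI intensities. Returns
#' `NA` (with a reason) when the slice cannot support detection: too few ROI
#' voxels for statistics, or a uniform ROI (SD = 0) under the default
#' zero-SD policy.
#'
#' @param stats One row of a [slice_statistics()] data frame (or a list with
#'   `mean`, `sd`, `n_voxels`).
#' @param config An [mr_config()].
#'
#' @return A list: `threshold` (numeric or NA), `valid` (logical), `reason`
#'   (`"ok"`, `"too_few_voxels"`, or `"zero_sd"`).
#' @export
slice_threshold <- function(stats, config = mr_config()) {
  n <- stats$n_voxels
  if (is.na(n) || n < config$min_voxels)
    return(list(threshold = NA_real_, valid = FALSE, reason = "too_few_voxels"))
  if (stats$sd == 0 && !config$zero_sd_detects)
    return(list(threshold = NA_real_, valid = FALSE, reason = "zero_sd"))
  list(threshold = stats$mean - config$k * stats$sd, valid = TRUE, reason = "ok")
}

#' Segment calcification on radial-VIBE by per-slice adaptive threshold
#'
#' For each slice of the analysis segment, computes the ROI mean and sample
#' SD (single pass over all ROI voxels, calcified ones included) and flags a
#' voxel as calcified iff it lies in the ROI and its intensity is at or below
#' `mean - k * SD` (inclusive: "at least k SD below"). No median filtering is
#' applied to MR images — it suppresses genuine calcium along with the noise.
#'
#' Slices with too few ROI voxels for statistics contribute zero area and are
#' flagged; uniform-intensity slices (SD = 0) contribute zero area under the
#' default policy. If *every* segment slice lacks valid statistics the result
#' would be indistinguishable from a truly calcium-free segment, so that case
#' is an error instead.
#'
#' @param volume An [image_volume()] (arbitrary intensity units).
#' @param roi An [roi_mask()] aligned to `volume`.
#' @param segment A [select_segment()] result.
#' @param config An [mr_config()].
#'
#' @return A `calcification_result`; its `per_slice` table carries the ROI
#'   mean, SD, threshold and validity of every slice for auditability.
#' @export
segment_calcium_mr <- function(volume, roi, segment, config = mr_config()) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "roi_mask"),
            inherits(segment, "segment_selection"), inherits(config, "mr_config"))
  check_aligned(volume, roi)
  st <- slice_statistics(volume, roi, segment)
  if (all(st$n_voxels < config$min_voxels))
    stop("no segment slice has enough ROI voxels for statistics (needed ",
         config$min_voxels, "); cannot distinguish 'no valid statistics' ",
         "from 'zero calcification'", call. = FALSE)

  va <- voxel_area_mm2(volume)
  dz <- slice_thickness_mm(volume)
  mask <- array(FALSE, dim = dim(volume$data))
  n_sl <- nrow(st)
  thr <- numeric(n_sl); valid <- logical(n_sl); reason <- character(n_sl)
  areas <- numeric(n_sl)
  for (r in seq_len(n_sl)) {
    t_r <- slice_threshold(st[r, ], config)
    thr[r] <- t_r$threshold; valid[r] <- t_r$valid; reason[r] <- t_r$reason
    if (!t_r$valid) next
    i <- st$slice_index[r] + 1L
    flag <- roi$data[, , i] & volume$data[, , i] <= t_r$threshold
    mask[, , i] <- flag
    areas[r] <- sum(flag) * va
  }
  per_slice <- data.frame(slice_index = st$slice_index, n_voxels = st$n_voxels,
                          mean = st$mean, sd = st$sd, threshold = thr,
                          valid = valid, reason = reason, area_mm2 = areas)
  new_calcification_result(per_slice = per_slice, mask = mask,
                           slice_thickness_mm = dz,
                           total_volume_mm3 = compute_volume(areas, dz),
                           config = config, modality = "MR")
}
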