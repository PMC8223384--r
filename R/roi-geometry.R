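#' Select the descending-aorta analysis segment
#'
#' Resolves a physical segment length (default 9 cm) into a half-open range of
#' axial slices, starting at a user-supplied anatomical landmark slice and
#' progressing in the configured direction. The landmark slice is included.
#' Slice indices are 0-based; the returned range is half-open
#' `[start, end)`.
#'
#' The number of slices is `round(length_mm / slice spacing)` with ties
#' rounded away from zero; the rounding is recorded in the result so the
#' realised physical length is auditable.
#'
#' @param volume An [image_volume()].
#' @param landmark 0-based index of the landmark slice (e.g., the top of the
#'   vertebra closest to the diaphragmatic surface of the heart).
#' @param length_mm Segment length in mm (default 90).
#' @param direction `"increasing"` or `"decreasing"`: which way slice indices
#'   run toward the superior direction in this volume. Required because axis
#'   orientation varies between files.
#'
#' @return An object of class `segment_selection` with fields `start`, `end`
#'   (half-open, 0-based), `slices` (integer vector), `n_slices`,
#'   `slice_spacing_mm`, `length_mm` (requested) and `realised_length_mm`.
#' @export
select_segment <- function(volume, landmark, length_mm = 90,
                           direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(inherits(volume, "image_volume"))
  nz <- dim(volume$data)[3]
  landmark <- as.integer(landmark)
  if (length(landmark) != 1L || is.na(landmark) || landmark < 0L || landmark >= nz)
    stop("landmark slice ", landmark, " is outside the volume [0, ", nz, ")",
         call. = FALSE)
  if (!is.finite(length_mm) || length_mm <= 0)
    stop("`length_mm` must be positive", call. = FALSE)

  dz <- slice_thickness_mm(volume)
  n <- round_half_away(length_mm / dz)
  if (n < 1L) stop("segment length resolves to zero slices", call. = FALSE)

  if (direction == "increasing") {
    start <- landmark
    end <- landmark + n
    if (end > nz)
      stop("segment needs ", n, " slices from landmark ", landmark,
           " but only ", nz - landmark, " remain (short by ", end - nz, ")",
           call. = FALSE)
    slices <- seq.int(start, end - 1L)
  } else {
    start <- landmark - n + 1L
    end <- landmark + 1L
    if (start < 0L)
      stop("segment needs ", n, " slices ending at landmark ", landmark,
           " but only ", landmark + 1L, " remain (short by ", -start, ")",
           call. = FALSE)
    slices <- seq.int(landmark, start)   # progression order: landmark first
  }

  structure(
    list(start = as.integer(start), end = as.integer(end),
         slices = as.integer(slices), n_slices = as.integer(n),
         direction = direction, slice_spacing_mm = dz,
         length_mm = length_mm, realised_length_mm = n * dz),
    class = "segment_selection"
  )
}

# round half away from zero (base round() is banker's)
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' @export
print.segment_selection <- function(x, ...) {
  cat(sprintf("<segment_selection> slices [%d, %d) (%d slices, %s), %.1f mm requested, %.1f mm realised\n",
              x$start, x$end, x$n_slices, x$direction, x$length_mm,
              x$realised_length_mm))
  invisible(x)
}

#' Per-slice ROI statistics
#'
#' Computes, for every slice in the segment, the ROI voxel count, mean and
#' sample standard deviation (n − 1 denominator) of intensity, and the ROI
#' area in mm². Slices whose ROI holds fewer than two voxels cannot yield a
#' standard deviation and are flagged `valid = FALSE` rather than dropped.
#'
#' @param volume An [image_volume()].
#' @param roi An [roi_mask()] aligned to `volume`.
#' @param segment A [select_segment()] result.
#'
#' @return A data frame with one row per segment slice: `slice_index`
#'   (0-based), `n_voxels`, `mean`, `sd`, `area_mm2`, `valid`.
#' @export
slice_statistics <- function(volume, roi, segment) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "roi_mask"),
            inherits(segment, "segment_selection"))
  check_aligned(volume, roi)
  va <- voxel_area_mm2(volume)
  rows <- lapply(segment$slices, function(s) {
    i <- s + 1L
    vals <- volume$data[, , i][roi$data[, , i]]
    n <- length(vals)
    if (n >= 2L) {
      data.frame(slice_index = s, n_voxels = n, mean = mean(vals),
                 sd = stats::sd(vals), area_mm2 = n * va, valid = TRUE)
    } else {
      data.frame(slice_index = s, n_voxels = n,
                 mean = if (n == 1L) vals else NA_real_, sd = NA_real_,
                 area_mm2 = n * va, valid = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write per-slice statistics to CSV
#'
#' @param stats A data frame from [slice_statistics()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_slice_statistics <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
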