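#' 3-D image volume with voxel spacing
#'
#' Lightweight container for a 3-D scalar field plus the physical metadata the
#' quantification pipeline needs: per-axis voxel spacing in millimetres, an
#' intensity-unit tag, and the identity of the axial (slice) axis. By
#' convention the third array axis is the slice axis; slices are indexed
#' 0-based throughout the package so that half-open slice ranges compose
#' without off-by-one ambiguity.
#'
#' @param data Numeric 3-D array of voxel intensities.
#' @param spacing Numeric vector of length 3, voxel spacing in mm per axis;
#'   all entries must be positive.
#' @param units Intensity unit tag: `"HU"` for calibrated CT attenuation, or
#'   `"arbitrary"` for MR signal intensity.
#'
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, units = c("arbitrary", "HU")) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)), " dimension(s)",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, units = units, slice_axis = 3L),
    class = "image_volume"
  )
}

#' Binary region-of-interest mask aligned to an image volume
#'
#' @param data Logical (or 0/1 numeric) 3-D array, voxel-for-voxel aligned to
#'   the companion [image_volume()].
#' @param spacing Voxel spacing in mm (same contract as [image_volume()]).
#'
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("ROI mask must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("ROI mask must not contain NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, units: %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$units))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<roi_mask> %d x %d x %d voxels, %d in ROI\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

# internal: check a mask is voxel-aligned to a volume
check_aligned <- function(volume, roi) {
  if (!identical(dim(volume$data), dim(roi$data)))
    stop("ROI mask (", paste(dim(roi$data), collapse = "x"),
         ") is not aligned to the volume (",
         paste(dim(volume$data), collapse = "x"), ")", call. = FALSE)
  if (max(abs(volume$spacing - roi$spacing)) > 1e-6)
    stop("ROI mask voxel spacing differs from the volume's", call. = FALSE)
  invisible(TRUE)
}

# internal: in-plane voxel area (mm^2) and slice thickness (mm)
voxel_area_mm2 <- function(x) x$spacing[1] * x$spacing[2]
slice_thickness_mm <- function(x) x$spacing[3]
voxel_volume_mm3 <- function(x) prod(x$spacing)
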