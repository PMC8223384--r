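#' Read a 3-D volume from a NIfTI-1 file
#'
#' Loads the voxel array and extracts the voxel spacing (mm) from the NIfTI
#' header. Only 3-D volumes are accepted; the third array axis is treated as
#' the axial slice axis.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param units Intensity-unit tag to attach (`"HU"` or `"arbitrary"`); NIfTI
#'   headers do not carry this reliably, so it comes from configuration.
#'
#' @return An [image_volume()].
#' @export
read_volume <- function(path, units = c("arbitrary", "HU")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), " axes (",
         paste(d, collapse = " x "), ") in ", path, call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("invalid voxel spacing in NIfTI header of ", path, call. = FALSE)
  image_volume(array(as.numeric(img), dim = d), sp, units)
}

#' Write an image volume or ROI mask to NIfTI-1
#'
#' @param x An [image_volume()] or [roi_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "image_volume")) {
    arr <- x$data
    sp <- x$spacing
  } else if (inherits(x, "roi_mask")) {
    arr <- array(as.integer(x$data), dim = dim(x$data))  # unsigned-byte style
    sp <- x$spacing
  } else {
    stop("`x` must be an image_volume or roi_mask", call. = FALSE)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask volume as an ROI
#'
#' Any nonzero voxel is in the ROI.
#'
#' @param path Path to a NIfTI mask.
#' @return An [roi_mask()].
#' @export
read_roi <- function(path) {
  v <- read_volume(path, units = "arbitrary")
  roi_mask(v$data != 0, v$spacing)
}

#' Read a cohort table from CSV
#'
#' Requires at least the two volume columns; extra columns are preserved
#' (with a warning listing them) so observer ratings and identifiers pass
#' through. Rows missing a required field are dropped with a logged count.
#'
#' @param path CSV path.
#' @param required Columns that must be present and complete.
#'
#' @return A data frame.
#' @export
read_cohort <- function(path,
                        required = c("ct_volume_mm3", "mr_volume_mm3")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("cohort file ", path, " is empty", call. = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  known <- c("subject_id", "ct_volume_mm3", "mr_volume_mm3", "cac_agatston",
             "likert_obs1", "likert_obs2")
  extra <- setdiff(names(df), known)
  if (length(extra))
    warning("cohort file has unknown column(s), preserved as-is: ",
            paste(extra, collapse = ", "), call. = FALSE)
  ok <- stats::complete.cases(df[required])
  if (any(!ok)) {
    message("dropped ", sum(!ok), " row(s) with missing required fields")
    df <- df[ok, , drop = FALSE]
  }
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort Data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write phantom ground truth to JSON
#'
#' Stores per-lesion and total true volumes (the voxel masks stay in
#' memory; they are reproducible from the phantom specification and seed).
#'
#' @param truth A `ground_truth`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(lesion_volumes_mm3 = truth$lesion_volumes_mm3,
         total_volume_mm3 = truth$total_volume_mm3,
         voxel_volume_mm3 = truth$voxel_volume_mm3),
    path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Write a calcification result to JSON
#'
#' Carries the per-slice table (areas and, for MR, the per-slice mean, SD
#' and threshold), total volume, slice thickness and the configuration echo.
#'
#' @param result A `calcification_result`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_calcification_result <- function(result, path) {
  stopifnot(inherits(result, "calcification_result"))
  jsonlite::write_json(
    list(modality = result$modality,
         total_volume_mm3 = result$total_volume_mm3,
         slice_thickness_mm = result$slice_thickness_mm,
         per_slice = result$per_slice,
         config = unclass(result$config)),
    path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}
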