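#' CT quantification configuration
#'
#' @param threshold_hu Calcification threshold in Hounsfield units; voxels at
#'   or above it count as calcified (default 130 HU, the conventional
#'   threshold, roughly 2 SD above unenhanced blood attenuation).
#' @param median_radius_mm Radius (mm) of the circular per-slice median
#'   filter used to suppress salt-and-pepper noise; 0 disables filtering.
#' @param min_lesion_area_mm2 Minimum in-plane lesion area counted by the
#'   Agatston score (default 1 mm²; the volume score applies no minimum).
#' @param connectivity In-plane neighbour rule for Agatston lesion labelling:
#'   4 or 8.
#'
#' @return An object of class `ct_config`.
#' @export
ct_config <- function(threshold_hu = 130, median_radius_mm = 3,
                      min_lesion_area_mm2 = 1, connectivity = 4L) {
  if (!is.finite(threshold_hu)) stop("threshold must be finite", call. = FALSE)
  if (!is.finite(median_radius_mm) || median_radius_mm < 0)
    stop("median filter radius must be >= 0", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(threshold_hu = threshold_hu,
                 median_radius_mm = median_radius_mm,
                 min_lesion_area_mm2 = min_lesion_area_mm2,
                 connectivity = as.integer(connectivity)),
            class = "ct_config")
}

#' Circular-kernel median filter, slice by slice
#'
#' Applies a 2-D median filter with a circular neighbourhood of the given
#' physical radius to each axial slice independently. A pixel belongs to the
#' neighbourhood if its centre lies within `radius_mm` of the centre pixel.
#' Borders are handled by edge replication. A radius of 0 returns the input
#' unchanged.
#'
#' @param volume An [image_volume()].
#' @param radius_mm Filter radius in mm.
#' @param allow_anisotropic If the in-plane spacing is anisotropic the kernel
#'   is elliptical in pixel space; this must be opted into explicitly.
#'
#' @return A filtered [image_volume()] with identical spacing and units.
#' @export
median_filter_ct <- function(volume, radius_mm = 3, allow_anisotropic = FALSE) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.finite(radius_mm) || radius_mm < 0)
    stop("radius must be >= 0", call. = FALSE)
  if (radius_mm == 0) return(volume)
  dx <- volume$spacing[1]; dy <- volume$spacing[2]
  if (abs(dx - dy) > 1e-9 && !allow_anisotropic)
    stop("in-plane spacing is anisotropic (", dx, " x ", dy,
         " mm); pass allow_anisotropic = TRUE to use an elliptical kernel",
         call. = FALSE)

  # kernel offsets: pixel centres within the physical radius
  ri <- floor(radius_mm / dx); rj <- floor(radius_mm / dy)
  off <- expand.grid(di = -ri:ri, dj = -rj:rj)
  keep <- (off$di * dx)^2 + (off$dj * dy)^2 <= radius_mm^2 + 1e-12
  off <- off[keep, , drop = FALSE]

  out <- volume$data
  nz <- dim(volume$data)[3]
  for (k in seq_len(nz)) {
    out[, , k] <- median_filter_slice(volume$data[, , k], off$di, off$dj)
  }
  image_volume(out, volume$spacing, volume$units)
}

# 2-D median over arbitrary offsets with edge replication
median_filter_slice <- function(slice, di, dj) {
  nr <- nrow(slice); nc <- ncol(slice)
  ii <- seq_len(nr); jj <- seq_len(nc)
  stack <- matrix(NA_real_, nrow = nr * nc, ncol = length(di))
  for (m in seq_along(di)) {
    si <- pmin(pmax(ii + di[m], 1L), nr)   # edge replication
    sj <- pmin(pmax(jj + dj[m], 1L), nc)
    stack[, m] <- slice[si, sj]
  }
  matrix(apply(stack, 1L, stats::median), nrow = nr, ncol = nc)
}

#' Segment calcification on CT by fixed HU threshold
#'
#' Flags a voxel as calcified iff it lies inside the ROI, inside the analysis
#' segment, and its attenuation is at or above the configured threshold
#' (inclusive). Any median filtering must already have been applied (or
#' deliberately disabled with radius 0); this operation only thresholds.
#'
#' @param volume An [image_volume()] in Hounsfield units.
#' @param roi An [roi_mask()] aligned to `volume`.
#' @param segment A [select_segment()] result.
#' @param config A [ct_config()].
#'
#' @return An object of class `calcification_result`: per-slice calcified
#'   areas (mm²), the 3-D calcification mask, slice thickness, total volume
#'   (mm³, area × thickness summed over slices) and the config used.
#' @export
segment_calcium_ct <- function(volume, roi, segment, config = ct_config()) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "roi_mask"),
            inherits(segment, "segment_selection"), inherits(config, "ct_config"))
  check_aligned(volume, roi)
  if (volume$units != "HU")
    stop("CT quantification requires a volume tagged in Hounsfield units; ",
         "got '", volume$units, "'", call. = FALSE)
  roi_counts <- vapply(segment$slices, function(s) sum(roi$data[, , s + 1L]),
                       integer(1))
  if (all(roi_counts == 0L))
    stop("ROI is empty on every segment slice", call. = FALSE)

  va <- voxel_area_mm2(volume)
  dz <- slice_thickness_mm(volume)
  mask <- array(FALSE, dim = dim(volume$data))
  areas <- numeric(segment$n_slices)
  for (idx in seq_along(segment$slices)) {
    i <- segment$slices[idx] + 1L
    flag <- roi$data[, , i] & volume$data[, , i] >= config$threshold_hu
    mask[, , i] <- flag
    areas[idx] <- sum(flag) * va
  }
  new_calcification_result(
    per_slice = data.frame(slice_index = segment$slices, area_mm2 = areas),
    mask = mask, slice_thickness_mm = dz,
    total_volume_mm3 = compute_volume(areas, dz),
    config = config, modality = "CT")
}

#' Calcium volume from per-slice areas
#'
#' The volume score: total calcium volume is the sum over slices of lesion
#' area times slice thickness. Independent of calcium density.
#'
#' @param areas_mm2 Numeric vector of per-slice calcified areas (mm²); may be
#'   empty.
#' @param thickness_mm Slice thickness in mm.
#'
#' @return Total volume in mm³.
#' @export
compute_volume <- function(areas_mm2, thickness_mm) {
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    stop("slice thickness must be positive", call. = FALSE)
  if (length(areas_mm2) == 0L) return(0)
  if (any(!is.finite(areas_mm2)) || any(areas_mm2 < 0))
    stop("per-slice areas must be finite and >= 0", call. = FALSE)
  sum(areas_mm2 * thickness_mm)
}

new_calcification_result <- function(per_slice, mask, slice_thickness_mm,
                                     total_volume_mm3, config, modality) {
  structure(list(per_slice = per_slice, mask = mask,
                 slice_thickness_mm = slice_thickness_mm,
                 total_volume_mm3 = total_volume_mm3,
                 config = config, modality = modality),
            class = "calcification_result")
}

#' @export
print.calcification_result <- function(x, ...) {
  cat(sprintf("<calcification_result> %s: total volume %.2f mm^3 over %d slices (%d voxels flagged)\n",
              x$modality, x$total_volume_mm3, nrow(x$per_slice), sum(x$mask)))
  invisible(x)
}

#' Agatston calcium score
#'
#' Scores calcified lesions on CT the conventional way: per axial slice,
#' voxels at or above the HU threshold inside the ROI are grouped into
#' connected lesions (4- or 8-connectivity in plane); each lesion with area
#' at or above the configured minimum contributes `area (mm²) × density
#' weight`, the weight determined by the lesion's maximum attenuation
#' (130–199 HU → 1, 200–299 → 2, 300–399 → 3, ≥ 400 → 4). The total is the
#' sum over all lesions on all slices.
#'
#' @param volume An [image_volume()] in Hounsfield units.
#' @param roi An [roi_mask()].
#' @param config A [ct_config()].
#' @param segment Optional [select_segment()] restriction; by default every
#'   slice is scored.
#'
#' @return An object of class `agatston_result` with the per-lesion table
#'   (`slice_index`, `area_mm2`, `max_hu`, `weight`, `score`) and the total.
#' @export
agatston_score <- function(volume, roi, config = ct_config(), segment = NULL) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "roi_mask"),
            inherits(config, "ct_config"))
  check_aligned(volume, roi)
  if (volume$units != "HU")
    stop("Agatston scoring requires Hounsfield units", call. = FALSE)
  va <- voxel_area_mm2(volume)
  slices0 <- if (is.null(segment)) seq_len(dim(volume$data)[3]) - 1L
             else segment$slices

  lesions <- list()
  for (s in slices0) {
    i <- s + 1L
    flag <- roi$data[, , i] & volume$data[, , i] >= config$threshold_hu
    if (!any(flag)) next
    lab <- label_components(flag, config$connectivity)
    for (lid in seq_len(max(lab))) {
      sel <- lab == lid
      area <- sum(sel) * va
      if (area < config$min_lesion_area_mm2) next
      mx <- max(volume$data[, , i][sel])
      w <- agatston_weight(mx)
      lesions[[length(lesions) + 1L]] <-
        data.frame(slice_index = s, area_mm2 = area, max_hu = mx,
                   weight = w, score = area * w)
    }
  }
  tab <- if (length(lesions)) do.call(rbind, lesions) else
    data.frame(slice_index = integer(), area_mm2 = numeric(),
               max_hu = numeric(), weight = integer(), score = numeric())
  structure(list(lesions = tab, total = sum(tab$score), config = config),
            class = "agatston_result")
}

agatston_weight <- function(max_hu) {
  if (max_hu >= 400) 4L else if (max_hu >= 300) 3L else if (max_hu >= 200) 2L else 1L
}

#' @export
print.agatston_result <- function(x, ...) {
  cat(sprintf("<agatston_result> total %.2f from %d lesion(s)\n",
              x$total, nrow(x$lesions)))
  invisible(x)
}

# in-plane connected-component labelling (flood fill), 4- or 8-connectivity
label_components <- function(mask, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    nbr <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    nbr <- cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))
    nbr <- nbr[!(nbr[, 1] == 0L & nbr[, 2] == 0L), , drop = FALSE]
  }
  current <- 0L
  todo <- which(mask)
  for (p in todo) {
    if (lab[p] != 0L) next
    current <- current + 1L
    queue <- p
    lab[p] <- current
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      qi <- ((q - 1L) %% nr) + 1L
      qj <- ((q - 1L) %/% nr) + 1L
      for (m in seq_len(nrow(nbr))) {
        ni <- qi + nbr[m, 1]; nj <- qj + nbr[m, 2]
        if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
        np <- (nj - 1L) * nr + ni
        if (mask[np] && lab[np] == 0L) {
          lab[np] <- current
          queue <- c(queue, np)
        }
      }
    }
  }
  lab
}
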