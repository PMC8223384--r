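#' Describe a calcified lesion for the digital phantom
#'
#' Lesions are wedges of the aortic wall annulus: a range of axial slices, an
#' angular extent around the centreline, and a radial depth measured outward
#' from the lumen-wall interface. On CT the lesion renders at a fixed
#' attenuation; on MR it renders hypointense, at a fraction of the wall
#' signal (or an absolute signal if given).
#'
#' @param slices Half-open 0-based slice range `c(first, end)`.
#' @param theta_deg Angular extent in degrees, `c(from, to)` with
#'   `0 <= from < to <= 360`.
#' @param depth_mm Radial depth into the wall from the lumen boundary (mm);
#'   must not exceed the wall thickness.
#' @param ct_hu CT attenuation of the lesion (HU). Use >= 130 HU for a lesion
#'   that is meant to be detectable.
#' @param mr_frac MR lesion signal as a fraction of the wall signal.
#' @param mr_signal Optional absolute MR lesion signal, overriding `mr_frac`.
#'
#' @return A `phantom_lesion` list.
#' @export
phantom_lesion <- function(slices, theta_deg = c(0, 90), depth_mm,
                           ct_hu = 800, mr_frac = 0.1, mr_signal = NULL) {
  stopifnot(length(slices) == 2L, length(theta_deg) == 2L)
  if (theta_deg[1] < 0 || theta_deg[2] > 360 || theta_deg[1] >= theta_deg[2])
    stop("theta_deg must satisfy 0 <= from < to <= 360", call. = FALSE)
  if (!is.finite(depth_mm) || depth_mm <= 0)
    stop("lesion depth must be positive", call. = FALSE)
  structure(list(slices = as.integer(slices), theta_deg = theta_deg,
                 depth_mm = depth_mm, ct_hu = ct_hu, mr_frac = mr_frac,
                 mr_signal = mr_signal),
            class = "phantom_lesion")
}

#' Specification of a paired CT/MR digital phantom
#'
#' The phantom models the descending aorta as a straight tube aligned with
#' the slice axis: a blood-filled lumen surrounded by a wall annulus, both of
#' which form the per-slice ROI. Calcified lesions are wedges of the wall.
#' The CT rendering is in Hounsfield units (blood pool ~40 HU) with additive
#' Gaussian noise followed by salt-and-pepper corruption; the MR rendering is
#' a proton-density-weighted magnitude image where calcification is
#' hypointense, with Rician noise. A degraded-quality factor > 1 multiplies
#' the within-ROI noise scale, emulating scans where in-aorta noise inflates
#' the adaptive threshold.
#'
#' @param shape Grid size in voxels per axis (default 64 x 64 x 40).
#' @param spacing Voxel spacing in mm (default 1.2 x 1.2 x 3.0: in-plane
#'   acquisition resolution with 3 mm reconstructed slices).
#' @param lumen_radius_mm Lumen radius (default 9.6 mm).
#' @param wall_thickness_mm Wall annulus thickness (default 4.8 mm).
#' @param center_mm Centreline position in mm `c(x, y)`; default grid centre.
#' @param lesions List of [phantom_lesion()]s.
#' @param ct_noise_sd SD of additive Gaussian CT noise (HU).
#' @param salt_pepper_prob Per-voxel probability of salt-and-pepper
#'   corruption on CT (half salt at +3000 HU, half pepper at -1000 HU).
#' @param mr_noise_scale Rician noise scale for MR (arbitrary units).
#' @param mr_degraded_factor Multiplier (>= 1) on the within-ROI MR noise
#'   scale; 1 means no degradation.
#' @param ct_blood_hu,ct_background_hu CT attenuation of blood/wall and of
#'   surrounding tissue.
#' @param mr_lumen_signal,mr_wall_signal,mr_background_signal MR signal
#'   levels (arbitrary units) of lumen, wall and surround. Lumen and wall
#'   deliberately differ so noiseless ROIs retain a nonzero SD.
#' @param seed Integer RNG seed; the same spec yields byte-identical output.
#'
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 40L),
                         spacing = c(1.2, 1.2, 3.0),
                         lumen_radius_mm = 9.6,
                         wall_thickness_mm = 4.8,
                         center_mm = NULL,
                         lesions = list(),
                         ct_noise_sd = 0,
                         salt_pepper_prob = 0,
                         mr_noise_scale = 0,
                         mr_degraded_factor = 1,
                         ct_blood_hu = 40,
                         ct_background_hu = -50,
                         mr_lumen_signal = 380,
                         mr_wall_signal = 420,
                         mr_background_signal = 30,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("grid shape must be 3 positive integers", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("all spacings must be > 0", call. = FALSE)
  if (is.null(center_mm))
    center_mm <- c(shape[1] * spacing[1] / 2, shape[2] * spacing[2] / 2)
  if (wall_thickness_mm <= 0 || lumen_radius_mm <= 0)
    stop("lumen radius and wall thickness must be positive", call. = FALSE)
  if (mr_degraded_factor < 1) stop("mr_degraded_factor must be >= 1", call. = FALSE)
  if (salt_pepper_prob < 0 || salt_pepper_prob > 1)
    stop("salt_pepper_prob must be in [0, 1]", call. = FALSE)
  for (les in lesions) {
    if (!inherits(les, "phantom_lesion"))
      stop("every lesion must be a phantom_lesion()", call. = FALSE)
    if (les$depth_mm > wall_thickness_mm + 1e-9)
      stop("lesion depth ", les$depth_mm, " mm exceeds wall thickness ",
           wall_thickness_mm, " mm: lesion lies outside the wall annulus",
           call. = FALSE)
    if (les$slices[1] < 0L || les$slices[2] > shape[3] || les$slices[1] >= les$slices[2])
      stop("lesion slice range [", les$slices[1], ", ", les$slices[2],
           ") is outside the grid [0, ", shape[3], ")", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing,
                 lumen_radius_mm = lumen_radius_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 center_mm = center_mm, lesions = lesions,
                 ct_noise_sd = ct_noise_sd,
                 salt_pepper_prob = salt_pepper_prob,
                 mr_noise_scale = mr_noise_scale,
                 mr_degraded_factor = mr_degraded_factor,
                 ct_blood_hu = ct_blood_hu,
                 ct_background_hu = ct_background_hu,
                 mr_lumen_signal = mr_lumen_signal,
                 mr_wall_signal = mr_wall_signal,
                 mr_background_signal = mr_background_signal,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a paired CT/MR phantom with known ground truth
#'
#' Renders the phantom described by a [phantom_spec()] into a CT volume (HU),
#' an MR volume (arbitrary units), the aortic ROI mask (lumen + wall on every
#' slice) and the calcification ground truth (per-lesion voxel masks and
#' analytic volumes: voxel count times voxel volume).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `ct`, `mr` ([image_volume()]s), `roi`
#'   ([roi_mask()]) and `truth` (class `ground_truth`: `lesion_masks`,
#'   `lesion_volumes_mm3`, `total_volume_mm3`, `mask`, `voxel_volume_mm3`).
#' @export
make_paired_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  dx <- spec$spacing[1]; dy <- spec$spacing[2]

  # in-plane geometry (voxel centres)
  x <- (seq_len(nx) - 0.5) * dx - spec$center_mm[1]
  y <- (seq_len(ny) - 0.5) * dy - spec$center_mm[2]
  r2d <- sqrt(outer(x^2, y^2, `+`))
  theta2d <- (atan2(outer(rep(1, nx), y), outer(x, rep(1, ny))) * 180 / pi) %% 360
  lumen2d <- r2d <= spec$lumen_radius_mm
  wall2d <- r2d > spec$lumen_radius_mm &
    r2d <= spec$lumen_radius_mm + spec$wall_thickness_mm
  roi2d <- lumen2d | wall2d

  ct <- array(spec$ct_background_hu, dim = spec$shape)
  mr <- array(spec$mr_background_signal, dim = spec$shape)
  roi <- array(FALSE, dim = spec$shape)
  for (k in seq_len(nz)) {
    ctk <- ct[, , k]; mrk <- mr[, , k]
    ctk[lumen2d] <- spec$ct_blood_hu; ctk[wall2d] <- spec$ct_blood_hu
    mrk[lumen2d] <- spec$mr_lumen_signal; mrk[wall2d] <- spec$mr_wall_signal
    ct[, , k] <- ctk; mr[, , k] <- mrk
    roi[, , k] <- roi2d
  }

  # paint lesions and collect truth
  vox_vol <- prod(spec$spacing)
  lesion_masks <- vector("list", length(spec$lesions))
  lesion_vols <- numeric(length(spec$lesions))
  truth_mask <- array(FALSE, dim = spec$shape)
  for (li in seq_along(spec$lesions)) {
    les <- spec$lesions[[li]]
    in2d <- wall2d & r2d <= spec$lumen_radius_mm + les$depth_mm &
      theta2d >= les$theta_deg[1] & theta2d < les$theta_deg[2]
    lm <- array(FALSE, dim = spec$shape)
    mr_sig <- if (!is.null(les$mr_signal)) les$mr_signal
              else les$mr_frac * spec$mr_wall_signal
    for (s in seq.int(les$slices[1], les$slices[2] - 1L)) {
      k <- s + 1L
      lm[, , k] <- in2d
      ctk <- ct[, , k]; mrk <- mr[, , k]
      ctk[in2d] <- les$ct_hu; mrk[in2d] <- mr_sig
      ct[, , k] <- ctk; mr[, , k] <- mrk
    }
    lesion_masks[[li]] <- lm
    lesion_vols[li] <- sum(lm) * vox_vol
    truth_mask <- truth_mask | lm
  }

  # noise, all drawn from one per-call RNG stream
  withr::with_seed(spec$seed, {
    if (spec$ct_noise_sd > 0)
      ct <- ct + array(stats::rnorm(length(ct), 0, spec$ct_noise_sd),
                       dim = spec$shape)
    if (spec$salt_pepper_prob > 0) {
      u <- array(stats::runif(length(ct)), dim = spec$shape)
      ct[u < spec$salt_pepper_prob / 2] <- 3000
      ct[u >= spec$salt_pepper_prob / 2 & u < spec$salt_pepper_prob] <- -1000
    }
    sigma <- array(spec$mr_noise_scale, dim = spec$shape)
    if (spec$mr_degraded_factor > 1)
      sigma[roi] <- sigma[roi] * spec$mr_degraded_factor
    if (any(sigma > 0)) {
      n1 <- array(stats::rnorm(length(mr)), dim = spec$shape)
      n2 <- array(stats::rnorm(length(mr)), dim = spec$shape)
      mr <- sqrt((mr + sigma * n1)^2 + (sigma * n2)^2)   # Rician magnitude
    }
  })

  truth <- structure(
    list(lesion_masks = lesion_masks, lesion_volumes_mm3 = lesion_vols,
         total_volume_mm3 = sum(lesion_vols), mask = truth_mask,
         voxel_volume_mm3 = vox_vol),
    class = "ground_truth")

  list(ct = image_volume(ct, spec$spacing, "HU"),
       mr = image_volume(mr, spec$spacing, "arbitrary"),
       roi = roi_mask(roi, spec$spacing),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d lesion(s), total %.2f mm^3\n",
              length(x$lesion_masks), x$total_volume_mm3))
  invisible(x)
}

#' Overlap metrics for a predicted calcification mask
#'
#' Dice coefficient, sensitivity and false-positive volume of a predicted
#' mask against the phantom ground truth. Dice is 1 only for identical
#' non-empty masks; when both masks are empty there is no overlap to
#' measure and Dice is `NA`.
#'
#' @param pred A logical 3-D array, a [roi_mask()] or a
#'   `calcification_result` (its mask is used).
#' @param truth A `ground_truth` from [make_paired_phantom()].
#'
#' @return A list: `dice`, `sensitivity`, `false_positive_volume_mm3`,
#'   `n_pred`, `n_truth`.
#' @export
score_segmentation <- function(pred, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  m <- if (inherits(pred, "calcification_result")) pred$mask
       else if (inherits(pred, "roi_mask")) pred$data
       else pred
  if (!is.array(m) || !identical(dim(m), dim(truth$mask)))
    stop("predicted mask is not aligned to the ground truth", call. = FALSE)
  m <- as.logical(m)
  tp <- sum(m & truth$mask)
  np <- sum(m); nt <- sum(truth$mask)
  dice <- if (np + nt == 0L) NA_real_ else 2 * tp / (np + nt)
  sens <- if (nt == 0L) NA_real_ else tp / nt
  list(dice = dice, sensitivity = sens,
       false_positive_volume_mm3 = (np - tp) * truth$voxel_volume_mm3,
       n_pred = np, n_truth = nt)
}
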