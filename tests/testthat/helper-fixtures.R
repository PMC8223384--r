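# Shared in-code fixtures.

# tiny single-slice volume with an explicit ROI; values in `roi_values` fill
# the ROI voxels, the rest of the slice sits at `background`
one_slice_volume <- function(roi_values, spacing = c(1.2, 1.2, 3.0),
                             shape = c(8L, 8L, 1L), background = 1000,
                             units = "arbitrary") {
  stopifnot(length(roi_values) <= shape[1] * shape[2])
  arr <- array(background, dim = shape)
  m <- array(FALSE, dim = shape)
  arr[seq_along(roi_values)] <- roi_values
  m[seq_along(roi_values)] <- TRUE
  list(volume = image_volume(arr, spacing, units),
       roi = roi_mask(m, spacing),
       segment = select_segment(image_volume(arr, spacing, units), 0L,
                                length_mm = spacing[3]))
}

# small default phantom used across tests (noiseless, three lesions)
demo_phantom <- function(seed = 1L, ...) {
  make_paired_phantom(phantom_spec(lesions = demo_lesions(), seed = seed, ...))
}

demo_segment <- function(phantom) select_segment(phantom$ct, 4L, 90)

# per-slice one-voxel boundary shell sizes of a truth mask (in-plane
# 4-neighbourhood): voxels addable by dilation, and voxels removable by
# erosion
shell_counts <- function(mask) {
  d <- dim(mask)
  inner <- 0L; outer <- 0L
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      nb <- c(if (i > 1) sl[i - 1, j] else FALSE,
              if (i < d[1]) sl[i + 1, j] else FALSE,
              if (j > 1) sl[i, j - 1] else FALSE,
              if (j < d[2]) sl[i, j + 1] else FALSE)
      if (sl[i, j] && any(!nb)) inner <- inner + 1L
      if (!sl[i, j] && any(nb)) outer <- outer + 1L
    }
  }
  list(inner = inner, outer = outer)
}
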