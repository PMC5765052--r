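# Global thresholding, connected-component cleanup, and the
# growth-plate-referenced VOI of the trabecular protocol.

#' Global threshold segmentation
#'
#' Foreground is every voxel with gray value greater than or equal to
#' `level` (inclusive; the inclusivity is fixed so that results are
#' deterministic). The default level of 40 is the operating point of the
#' trabecular protocol on 8-bit micro-CT reconstructions.
#'
#' @param vol a `voxel_volume`.
#' @param level gray-level threshold (default 40).
#' @return a `binary_mask` sharing the volume's geometry.
#' @export
threshold_mask <- function(vol, level = 40) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.finite(level)) stop_bad("`level` must be finite")
  binary_mask(vol$data >= level, vol$spacing, vol$origin)
}

#' Keep the largest connected component
#'
#' Retains only the largest foreground component. Ties are broken in favour
#' of the component containing the smallest linear voxel index. Foreground
#' connectivity defaults to 26 (with the usual 6-connected background
#' duality left to the caller's interpretation).
#'
#' @param mask a `binary_mask` with at least one foreground voxel.
#' @param connectivity 6 or 26.
#' @return a `binary_mask`.
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6, 26)) stop_bad("connectivity must be 6 or 26")
  if (!any(mask$data)) stop_bad("mask is empty")
  lab <- cpp_label_components(as.vector(mask$data), dim(mask$data),
                              as.integer(connectivity))
  counts <- tabulate(lab[lab > 0L])
  # labels are assigned in scan order, so among equal-sized components the
  # smallest label is the one whose minimal voxel index is lowest
  best <- which(counts == max(counts))[1]
  binary_mask(array(lab == best, dim(mask$data)), mask$spacing, mask$origin)
}

#' VOI specification for trabecular analysis
#'
#' The trabecular volume of interest starts `offset_mm` from the
#' growth-plate reference slice toward the diaphysis and extends
#' `extent_mm` along the bone axis (array axis 1). Defaults follow the
#' standard protocol: 0.1 mm offset, 0.5 mm extent.
#'
#' @param reference_slice 1-based index of the growth-plate reference plane
#'   along axis 1.
#' @param offset_mm distance from the reference plane to the VOI start.
#' @param extent_mm VOI length along the axis.
#' @param direction +1 or -1: which way along axis 1 is "toward the
#'   diaphysis".
#' @return an object of class `voi_spec`.
#' @export
voi_spec <- function(reference_slice, offset_mm = 0.1, extent_mm = 0.5,
                     direction = 1) {
  if (offset_mm < 0) stop_bad("offset_mm must be >= 0")
  if (extent_mm <= 0) stop_bad("extent_mm must be > 0")
  if (!direction %in% c(-1, 1)) stop_bad("direction must be +1 or -1")
  structure(list(reference_slice = as.integer(reference_slice),
                 offset_mm = offset_mm, extent_mm = extent_mm,
                 direction = direction),
            class = "voi_spec")
}

# round half away from zero; mm distances land on an 8.6 um grid so the
# rounding rule must be fixed explicitly (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Build the trabecular VOI from a mask
#'
#' Converts the mm offsets of a [voi_spec()] to slice counts with
#' round-half-away-from-zero, then zeroes the mask outside the half-open
#' slice range `[start, stop)` along axis 1.
#'
#' @param mask a `binary_mask`.
#' @param spec a `voi_spec`.
#' @return a `binary_mask` restricted to the VOI slab.
#' @export
build_voi <- function(mask, spec) {
  stopifnot(inherits(mask, "binary_mask"), inherits(spec, "voi_spec"))
  s1 <- mask$spacing[1]
  n1 <- dim(mask$data)[1]
  off <- round_half_away(spec$offset_mm / s1)
  ext <- round_half_away(spec$extent_mm / s1)
  if (ext < 1) stop_bad("VOI extent smaller than one slice spacing")
  start <- spec$reference_slice + spec$direction * off
  stop_ <- start + spec$direction * ext
  slices <- if (spec$direction > 0) seq(start, stop_ - 1L) else
    seq(stop_ + 1L, start)
  if (min(slices) < 1L || max(slices) > n1)
    stop_bad("VOI exits the volume (slices ", min(slices), "..",
             max(slices), " of ", n1, ")")
  out <- array(FALSE, dim(mask$data))
  out[slices, , ] <- mask$data[slices, , , drop = FALSE]
  binary_mask(out, mask$spacing, mask$origin)
}

#' Slab mask of the VOI region itself
#'
#' The all-true mask over the VOI slice range, used as the total-volume
#' reference (TV) for BV/TV when the whole slab is the sample volume.
#'
#' @inheritParams build_voi
#' @return a `binary_mask`.
#' @export
voi_region <- function(mask, spec) {
  full <- binary_mask(array(TRUE, dim(mask$data)), mask$spacing, mask$origin)
  build_voi(full, spec)
}
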