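# Skull bone volume, brain volume from slice-wise segmentation, and
# foramen magnum morphometry.

#' Skull bone volume
#'
#' Thresholds the CT volume, keeps the largest connected bone component
#' and returns its voxel-count volume. Monotone non-increasing in the
#' threshold level.
#'
#' @param vol a `voxel_volume`.
#' @param level threshold gray level (default 40).
#' @return volume in mm^3.
#' @export
skull_volume <- function(vol, level = 40) {
  mask <- threshold_mask(vol, level)
  if (!any(mask$data)) stop_bad("empty segmentation at level ", level)
  volume_mm3(largest_component(mask))
}

#' Brain volume from segmented coronal slices
#'
#' The MRI protocol segments the brain slice by slice in the coronal
#' plane; the volume is the summed slice area times the slice thickness.
#'
#' @param slice_masks list of 2D logical matrices, one per coronal slice,
#'   all of the same shape.
#' @param slice_thickness_mm slice thickness, mm (default 0.5, the
#'   standard T2 protocol).
#' @param in_plane_spacing length-2 in-plane voxel spacing, mm.
#' @return volume in mm^3.
#' @export
brain_volume <- function(slice_masks, slice_thickness_mm = 0.5,
                         in_plane_spacing) {
  if (length(slice_masks) == 0L) stop_bad("no slices supplied")
  d <- dim(slice_masks[[1]])
  ok <- vapply(slice_masks, function(m) is.logical(m) &&
                 identical(dim(m), d), TRUE)
  if (!all(ok)) stop_bad("slices must be logical matrices of one shape")
  npix <- sum(vapply(slice_masks, sum, 0))
  if (npix == 0L) stop_bad("all slices are empty")
  npix * prod(in_plane_spacing) * slice_thickness_mm
}

#' Foramen boundary loop
#'
#' The circumference of the foramen magnum is measured along the rim of
#' the aperture on the 3D skull surface: the longest closed loop of
#' boundary edges (edges used by exactly one face). The mesh must be open
#' (a watertight mesh has no rim and is rejected).
#'
#' @param mesh a `surface_mesh` with at least one boundary loop.
#' @return a closed `polyline3d` tracing the rim; its length is the
#'   geodesic circumference.
#' @export
foramen_boundary <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L)
    stop_bad("mesh is watertight: no boundary loop to measure")
  loops[[1]]
}

#' Foramen morphometrics
#'
#' Circumference (rim loop length), transverse and sagittal diameters
#' (extents of the rim points along two supplied orthogonal unit axes)
#' and the elliptical area 1/4 * pi * Dt * Ds.
#'
#' @param loop closed `polyline3d` rim with at least 3 points.
#' @param transverse_axis,sagittal_axis orthogonal unit 3-vectors; the
#'   defaults take world axis 2 as transverse and axis 3 as sagittal.
#' @return object of class `foramen_result`: list with
#'   `circumference_mm`, `d_t_mm`, `d_s_mm`, `area_mm2`.
#' @export
foramen_metrics <- function(loop, transverse_axis = c(0, 1, 0),
                            sagittal_axis = c(0, 0, 1)) {
  stopifnot(inherits(loop, "polyline3d"))
  if (!loop$closed || nrow(loop$points) < 3L)
    stop_bad("`loop` must be a closed polyline with >= 3 points")
  ta <- transverse_axis / sqrt(sum(transverse_axis^2))
  sa <- sagittal_axis / sqrt(sum(sagittal_axis^2))
  if (abs(sum(ta * sa)) > 1e-8) stop_bad("axes must be orthogonal")
  pt <- loop$points %*% ta
  ps <- loop$points %*% sa
  d_t <- diff(range(pt))
  d_s <- diff(range(ps))
  if (d_t <= 0 || d_s <= 0)
    stop_bad("degenerate loop: zero extent along a measurement axis")
  res <- list(circumference_mm = polyline_length(loop),
              d_t_mm = d_t, d_s_mm = d_s,
              area_mm2 = pi / 4 * d_t * d_s)
  class(res) <- "foramen_result"
  res
}

#' @export
print.foramen_result <- function(x, ...) {
  cat(sprintf(paste0("<foramen_result> circumference %.4f mm, Dt %.4f mm, ",
                     "Ds %.4f mm, area %.4f mm^2\n"),
              x$circumference_mm, x$d_t_mm, x$d_s_mm, x$area_mm2))
  invisible(x)
}
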