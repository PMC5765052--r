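# Trabecular microarchitecture: BV/TV, Tb.Th, Tb.N.

#' Bone volume fraction (BV/TV)
#'
#' Fraction of the sample volume occupied by bone: foreground voxels of
#' the bone mask inside the VOI divided by the VOI voxel count.
#'
#' @param mask bone `binary_mask`.
#' @param voi `binary_mask` of the sample volume (same geometry).
#' @return dimensionless fraction in \[0, 1\].
#' @export
bv_tv <- function(mask, voi) {
  stopifnot(inherits(mask, "binary_mask"), inherits(voi, "binary_mask"))
  if (!identical(dim(mask$data), dim(voi$data)) ||
      !isTRUE(all.equal(mask$spacing, voi$spacing)))
    stop_bad("mask and VOI must share geometry")
  ntv <- sum(voi$data)
  if (ntv == 0L) stop_bad("empty VOI")
  sum(mask$data & voi$data) / ntv
}

#' Trabecular thickness (Tb.Th)
#'
#' Model-independent local thickness by maximal inscribed spheres
#' (Hildebrand-Ruegsegger): for every bone voxel, the diameter of the
#' largest sphere that both contains the voxel and fits inside the
#' structure; Tb.Th is the mean over all bone voxels. Sphere radii are
#' Euclidean distances to the nearest background voxel centre, computed in
#' physical mm so anisotropic grids are handled exactly.
#'
#' @param mask bone `binary_mask` (non-empty).
#' @return mean local thickness in mm.
#' @export
tb_th <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop_bad("mask is empty")
  th <- local_thickness(mask)
  mean(th$data[mask$data])
}

#' Local thickness field
#'
#' The underlying voxel-wise thickness map used by [tb_th()], as a
#' `voxel_volume` of sphere diameters (mm), zero outside the structure.
#'
#' @inheritParams tb_th
#' @return a `voxel_volume`.
#' @export
local_thickness <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  th <- cpp_local_thickness(as.vector(mask$data), dim(mask$data),
                            mask$spacing)
  voxel_volume(array(th, dim(mask$data)), mask$spacing, mask$origin)
}

#' Trabecular number (Tb.N)
#'
#' Plate-model trabecular number, (BV/TV) / Tb.Th, in 1/mm. Exact on
#' parallel-plate structures, where it equals one over the plate period.
#'
#' @param bvtv bone volume fraction.
#' @param tbth trabecular thickness, mm (> 0).
#' @return plates per mm.
#' @export
tb_n <- function(bvtv, tbth) {
  if (!is.finite(tbth) || tbth <= 0) stop_bad("Tb.Th must be > 0")
  bvtv / tbth
}

#' Full trabecular analysis inside a growth-plate-referenced VOI
#'
#' Convenience wrapper running the standard protocol: threshold the
#' volume, restrict to the VOI (a [voi_spec()] slab or an explicit mask;
#' disconnected trabeculae are all retained), and compute BV/TV against
#' the VOI, Tb.Th and Tb.N.
#'
#' @param vol a `voxel_volume` (or a precomputed bone `binary_mask`).
#' @param spec a [voi_spec()]; `NULL` analyses the whole volume.
#' @param level threshold gray level (default 40).
#' @param voi optional explicit sample-volume `binary_mask`, overriding
#'   `spec` (e.g. when the VOI was delineated externally).
#' @return object of class `trabecular_result`: list with `bv_tv`,
#'   `tb_th`, `tb_n`, `bone_volume_mm3`, `total_volume_mm3` and a
#'   `params` record of the settings used.
#' @export
trabecular_metrics <- function(vol, spec = NULL, level = 40, voi = NULL) {
  mask <- if (inherits(vol, "binary_mask")) vol else
    threshold_mask(vol, level)
  if (!is.null(voi)) {
    bone <- binary_mask(mask$data & voi$data, mask$spacing, mask$origin)
  } else if (is.null(spec)) {
    voi <- binary_mask(array(TRUE, dim(mask$data)), mask$spacing, mask$origin)
    bone <- mask
  } else {
    voi <- voi_region(mask, spec)
    bone <- build_voi(mask, spec)
  }
  bvtv <- bv_tv(bone, voi)
  if (!any(bone$data)) stop_bad("no bone voxels inside the VOI")
  tbth <- tb_th(bone)
  res <- list(bv_tv = bvtv, tb_th = tbth, tb_n = tb_n(bvtv, tbth),
              bone_volume_mm3 = volume_mm3(bone),
              total_volume_mm3 = volume_mm3(voi),
              params = list(level = level,
                            tb_n_model = "plate (BV/TV / Tb.Th)",
                            voi = spec))
  class(res) <- "trabecular_result"
  res
}

#' @export
print.trabecular_result <- function(x, ...) {
  cat(sprintf(paste0("<trabecular_result>\n  BV/TV  %.4f\n  Tb.Th  %.4f mm\n",
                     "  Tb.N   %.4f 1/mm\n  BV %.4f mm^3 / TV %.4f mm^3\n"),
              x$bv_tv, x$tb_th, x$tb_n, x$bone_volume_mm3,
              x$total_volume_mm3))
  invisible(x)
}
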