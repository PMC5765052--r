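# Growth-plate 3D parameters: volume, two-surface thickness (mean,
# histogram, topographic map), and the volume/thickness ratio used as a
# surface-area surrogate.

#' Growth-plate volume
#'
#' Voxel-count volume of a segmented growth-plate mask.
#'
#' @param mask a non-empty `binary_mask`.
#' @return volume in mm^3.
#' @export
gp_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop_bad("mask is empty")
  volume_mm3(mask)
}

#' Split a plate mask into its two bounding surfaces
#'
#' Extracts the isosurface of the plate and partitions it into the two
#' open sheets facing along +axis and -axis, using the sign of each face
#' normal's component along `axis`. Rim faces, whose unit normal is nearly
#' perpendicular to the axis (|component| < `rim_tolerance`), are
#' discarded so that the two sheets are open surfaces whose mutual
#' distance is the plate thickness.
#'
#' @param mask plate-like single-component `binary_mask`.
#' @param axis axis index (1, 2 or 3) of the plate normal direction;
#'   default 1, the longitudinal axis.
#' @param rim_tolerance faces with |unit normal component| below this are
#'   treated as rim and dropped.
#' @param smooth_sigma_vox passed to [isosurface()].
#' @return list with `surface_mesh` elements `proximal` (facing -axis,
#'   i.e. the sheet whose outward normal points toward lower axis
#'   coordinates) and `distal`.
#' @export
split_surfaces <- function(mask, axis = 1, rim_tolerance = 0.5,
                           smooth_sigma_vox = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  mesh <- isosurface(mask, smooth_sigma_vox = smooth_sigma_vox)
  n <- face_normals(mesh$vertices, mesh$faces)[, axis]
  a <- face_areas(mesh$vertices, mesh$faces)
  # a plate has a thin rim: if a large share of the surface is rim the
  # mask has no plate orientation along this axis (e.g. a sphere)
  rim_frac <- sum(a[abs(n) <= rim_tolerance]) / sum(a)
  if (rim_frac > 0.35)
    stop_bad("mask has no plate orientation along axis ", axis,
             " (rim fraction ", signif(rim_frac, 2), ")")
  prox <- mesh$faces[n < -rim_tolerance, , drop = FALSE]
  dist <- mesh$faces[n > rim_tolerance, , drop = FALSE]
  if (nrow(prox) == 0L || nrow(dist) == 0L)
    stop_bad("mask has no plate orientation along axis ", axis,
             " (one of the sheets is empty)")
  list(proximal = subset_mesh(mesh, prox), distal = subset_mesh(mesh, dist))
}

# re-index a face subset into a standalone mesh
subset_mesh <- function(mesh, faces) {
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[faces], ncol = 3))
}

#' Two-surface growth-plate thickness
#'
#' For every vertex of the proximal sheet, the thickness sample is the
#' distance to the nearest point of the distal sheet. The summary scalar
#' is the area-weighted mean of these samples; the full histogram is
#' returned alongside, as is a topographic thickness map gridded over the
#' plate's in-plane footprint (orthographic projection perpendicular to
#' `axis`).
#'
#' @param proximal,distal `surface_mesh` sheets from [split_surfaces()].
#' @param axis plate normal axis (1, 2 or 3) used for the map projection.
#' @param breaks histogram bin specification (passed to [hist()]).
#' @param map_bin_mm in-plane bin size of the thickness map; default twice
#'   the median mesh edge length.
#' @return object of class `gp_thickness`: list with `mean_mm`,
#'   `histogram` (a `hist` object over the samples), `samples_mm`,
#'   `weights`, and `map` (list with `axis1`, `axis2` bin centres and a
#'   matrix `thickness_mm` of per-bin means, NA off the footprint).
#' @export
gp_thickness <- function(proximal, distal, axis = 1, breaks = 30,
                         map_bin_mm = NULL) {
  stopifnot(inherits(proximal, "surface_mesh"),
            inherits(distal, "surface_mesh"))
  q <- proximal$vertices
  ref <- distal$vertices
  cell <- max(stats::median(edge_lengths(distal)) * 4, 1e-6)
  d <- cpp_nn_dist(q, ref, cell)
  w <- vertex_area_weights(proximal)
  mean_mm <- sum(d * w) / sum(w)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  inplane <- setdiff(1:3, axis)
  if (is.null(map_bin_mm))
    map_bin_mm <- 2 * stats::median(edge_lengths(proximal))
  u <- q[, inplane[1]]; v <- q[, inplane[2]]
  ub <- floor((u - min(u)) / map_bin_mm) + 1L
  vb <- floor((v - min(v)) / map_bin_mm) + 1L
  m <- unname(tapply(d, list(factor(ub, levels = seq_len(max(ub))),
                             factor(vb, levels = seq_len(max(vb)))), mean))
  map <- list(axis1 = min(u) + (seq_len(nrow(m)) - 0.5) * map_bin_mm,
              axis2 = min(v) + (seq_len(ncol(m)) - 0.5) * map_bin_mm,
              thickness_mm = m)
  structure(list(mean_mm = mean_mm, histogram = h, samples_mm = d,
                 weights = w, map = map),
            class = "gp_thickness")
}

edge_lengths <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
}

#' @export
print.gp_thickness <- function(x, ...) {
  cat(sprintf("<gp_thickness> mean %.4f mm over %d surface samples\n",
              x$mean_mm, length(x$samples_mm)))
  invisible(x)
}

#' Plot the topographic thickness map
#'
#' @param x a `gp_thickness`.
#' @param ... passed to [graphics::image()].
#' @export
plot.gp_thickness <- function(x, ...) {
  graphics::image(x$map$axis1, x$map$axis2, x$map$thickness_mm,
                  xlab = "mm", ylab = "mm",
                  main = "Growth-plate thickness (mm)", ...)
  invisible(x)
}

#' Volume/thickness ratio (surface-area surrogate)
#'
#' The ratio of growth-plate volume to mean thickness approximates the
#' plate's footprint surface area; it is exact for constant-thickness
#' plates.
#'
#' @param volume_mm3 plate volume, mm^3.
#' @param thickness_mm mean thickness, mm (> 0).
#' @return area surrogate in mm^2.
#' @export
gp_ratio <- function(volume_mm3, thickness_mm) {
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    stop_bad("thickness must be > 0")
  volume_mm3 / thickness_mm
}

#' Full growth-plate analysis
#'
#' Volume, two-surface thickness (mean + histogram + map) and the
#' volume/thickness area surrogate, from a segmented plate mask.
#'
#' @inheritParams split_surfaces
#' @param ... passed to [gp_thickness()].
#' @return object of class `growthplate_result`: list with `volume_mm3`,
#'   `thickness_mean_mm`, `ratio_mm2`, `thickness` (the `gp_thickness`
#'   object) and `surfaces`.
#' @export
growthplate_metrics <- function(mask, axis = 1, rim_tolerance = 0.5, ...) {
  vol <- gp_volume(mask)
  sh <- split_surfaces(mask, axis = axis, rim_tolerance = rim_tolerance)
  th <- gp_thickness(sh$proximal, sh$distal, axis = axis, ...)
  res <- list(volume_mm3 = vol, thickness_mean_mm = th$mean_mm,
              ratio_mm2 = gp_ratio(vol, th$mean_mm), thickness = th,
              surfaces = sh)
  class(res) <- "growthplate_result"
  res
}

#' @export
print.growthplate_result <- function(x, ...) {
  cat(sprintf(paste0("<growthplate_result>\n  volume     %.4f mm^3\n",
                     "  thickness  %.4f mm\n  ratio      %.4f mm^2\n"),
              x$volume_mm3, x$thickness_mean_mm, x$ratio_mm2))
  invisible(x)
}
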