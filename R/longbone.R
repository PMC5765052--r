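# Curved 3D bone-length measurement.

#' Curved length from seed points
#'
#' The curved length of a bone is the length of the piecewise-linear
#' polyline through the seed points, mimicking an interactive 3D length
#' tool. No spline smoothing is applied by default; `spline = TRUE`
#' resamples the seeds through a natural cubic spline first (off by
#' default so that the measurement is exactly the polyline the user drew).
#'
#' @param seeds a `polyline3d` (or an n x 3 matrix) of at least 2 seed
#'   points in world mm.
#' @param spline resample through a cubic spline before measuring.
#' @param n_spline number of spline sample points.
#' @return length in mm; always at least the straight-line distance
#'   between the endpoints.
#' @export
curved_length <- function(seeds, spline = FALSE, n_spline = 200) {
  if (!inherits(seeds, "polyline3d")) seeds <- polyline3d(seeds)
  if (!spline) return(polyline_length(seeds))
  p <- seeds$points
  t0 <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  tt <- seq(0, t0[length(t0)], length.out = n_spline)
  ps <- vapply(1:3, function(d) stats::spline(t0, p[, d], xout = tt)$y,
               numeric(length(tt)))
  polyline_length(polyline3d(ps))
}

#' Automatic centerline of a tubular mask
#'
#' Extracts an ordered medial polyline through a single tubular component:
#' the two foreground voxels farthest apart in grid-geodesic distance are
#' found by a double Dijkstra sweep, then the path between them is traced
#' with edge costs penalising departure from the medial axis (low distance-
#' transform values), and finally resampled and locally averaged to remove
#' voxel-level zigzag. Masks without an unambiguous two-tip axis (e.g. a
#' sphere, where the tip separation is comparable to the local radius) are
#' rejected.
#'
#' @param mask a `binary_mask` containing a single tubular component.
#' @param n_points number of points in the returned polyline.
#' @param medial_penalty weight of the off-axis cost term; larger values
#'   hug the medial axis more tightly.
#' @param smooth_window width (points, odd) of the moving-average filter
#'   applied to the densely resampled path.
#' @param min_aspect minimal ratio of tip-to-tip geodesic length to the
#'   maximal inscribed radius for the mask to count as tubular.
#' @return a `polyline3d` with `n_points` points.
#' @export
centerline_from_mask <- function(mask, n_points = 100, medial_penalty = 20,
                                 smooth_window = 11, min_aspect = 6) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop_bad("mask is empty")
  dm <- dim(mask$data)
  fg <- as.vector(mask$data)
  d2 <- cpp_edt_sq(fg, dm, mask$spacing)
  r <- sqrt(pmax(d2, 0))
  rmax <- max(r)
  # medial node cost: 1 at the axis (r = rmax), 1 + penalty at the surface
  ncost <- 1 + medial_penalty * (rmax - r) / rmax
  unit <- rep(1, length(fg))
  # tips live on the medial axis: restrict the farthest-pair search to
  # voxels whose inscribed radius is close to the maximum, then double
  # sweep with unit cost to find the two geodesic tips
  medial <- fg & r >= 0.85 * rmax
  src <- which(medial)[1]
  g1 <- cpp_grid_geodesic(fg, dm, mask$spacing, src, unit)
  a <- which.max(ifelse(is.finite(g1$dist) & medial, g1$dist, -1))
  g2 <- cpp_grid_geodesic(fg, dm, mask$spacing, a, unit)
  b <- which.max(ifelse(is.finite(g2$dist) & medial, g2$dist, -1))
  tip_sep <- g2$dist[b]
  if (!is.finite(tip_sep) || tip_sep < min_aspect * rmax)
    stop_bad("mask has no unambiguous tubular axis ",
             "(tip separation ", signif(tip_sep, 3), " mm vs radius ",
             signif(rmax, 3), " mm)")
  # medial-weighted path from a to b
  g3 <- cpp_grid_geodesic(fg, dm, mask$spacing, a, ncost)
  path_idx <- integer(0)
  cur <- b
  while (!is.na(cur)) {
    path_idx <- c(cur, path_idx)
    cur <- g3$parent[cur]
  }
  ijk <- cbind((path_idx - 1L) %% dm[1],
               ((path_idx - 1L) %/% dm[1]) %% dm[2],
               (path_idx - 1L) %/% (dm[1] * dm[2])) + 1L
  pts <- world_from_index(mask, ijk)
  pts <- resample_polyline(pts, max(4L * n_points, 200L))
  pts <- smooth_polyline(pts, smooth_window)
  polyline3d(resample_polyline(pts, n_points))
}

# resample a polyline at n equally spaced arc-length positions
resample_polyline <- function(p, n) {
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  keep <- !duplicated(s)
  p <- p[keep, , drop = FALSE]; s <- s[keep]
  tt <- seq(0, s[length(s)], length.out = n)
  vapply(1:3, function(d) stats::approx(s, p[, d], xout = tt)$y,
         numeric(n))
}

# centred moving average with shrinking window at the ends (endpoints fixed)
smooth_polyline <- function(p, window) {
  if (window < 3) return(p)
  n <- nrow(p)
  half <- window %/% 2
  out <- p
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    if (h > 0) out[i, ] <- colMeans(p[(i - h):(i + h), , drop = FALSE])
  }
  out
}
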