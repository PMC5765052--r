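# Isosurface extraction and mesh topology helpers.

#' Isosurface of a mask or volume
#'
#' Extracts a triangulated isosurface by marching tetrahedra. For binary
#' masks the 0/1 indicator is first smoothed with a small Gaussian
#' (`smooth_sigma_vox` voxels per axis) and contoured at 0.5, which places
#' the surface at the half-voxel boundary and suppresses voxelization
#' staircase bias in areas and boundary lengths. Triangle normals point
#' outward (toward low field values).
#'
#' @param x a `binary_mask` or `voxel_volume`.
#' @param level iso level; default 0.5 for masks, otherwise required.
#' @param smooth_sigma_vox Gaussian sigma in voxels applied before
#'   contouring (0 disables smoothing).
#' @return a `surface_mesh`.
#' @export
isosurface <- function(x, level = NULL, smooth_sigma_vox = 1) {
  if (inherits(x, "binary_mask")) {
    field <- array(as.numeric(x$data), dim(x$data))
    if (is.null(level)) level <- 0.5
  } else if (inherits(x, "voxel_volume")) {
    field <- x$data
    if (is.null(level)) stop_bad("`level` required for gray volumes")
  } else stop_bad("`x` must be a binary_mask or voxel_volume")
  if (smooth_sigma_vox > 0)
    field <- array(cpp_gauss3(as.vector(field), dim(field),
                              rep(smooth_sigma_vox, 3)), dim(field))
  res <- cpp_marching_tetrahedra(as.vector(field), dim(field), level,
                                 x$spacing, x$origin)
  if (nrow(res$vertices) == 0L)
    stop_bad("isosurface is empty at level ", level)
  surface_mesh(res$vertices, res$faces)
}

# edges used by exactly one face, as an e x 2 matrix of vertex indices
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  single <- names(tab)[tab == 1L]
  e[key %in% single, , drop = FALSE]
}

#' Boundary loops of an open mesh
#'
#' Edges used by exactly one face are chained into closed loops. Returns
#' a list of closed `polyline3d`s, longest first.
#'
#' @param mesh a `surface_mesh`.
#' @return list of closed `polyline3d` objects (possibly empty for a
#'   watertight mesh).
#' @export
boundary_loops <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L) return(list())
  # adjacency between boundary vertices
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  visited_edge <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (r in seq_len(nrow(be))) {
    a <- be[r, 1]; b <- be[r, 2]
    if (!is.null(visited_edge[[ekey(a, b)]])) next
    path <- c(a, b)
    visited_edge[[ekey(a, b)]] <- TRUE
    repeat {
      cur <- path[length(path)]
      nxts <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (cand in nxts) {
        if (is.null(visited_edge[[ekey(cur, cand)]])) { nxt <- cand; break }
      }
      if (is.na(nxt)) break
      visited_edge[[ekey(cur, nxt)]] <- TRUE
      if (nxt == path[1]) break
      path <- c(path, nxt)
    }
    if (length(path) >= 3L)
      loops[[length(loops) + 1L]] <-
        polyline3d(mesh$vertices[path, , drop = FALSE], closed = TRUE)
  }
  if (length(loops) == 0L) return(list())
  loops[order(vapply(loops, polyline_length, 0), decreasing = TRUE)]
}

# per-vertex area weights: one third of the area of incident faces
vertex_area_weights <- function(mesh) {
  a <- face_areas(mesh$vertices, mesh$faces)
  w <- numeric(nrow(mesh$vertices))
  for (col in 1:3) {
    acc <- tapply(a, mesh$faces[, col], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + acc / 3
  }
  w
}
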