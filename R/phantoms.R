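# Analytic phantoms with closed-form ground truth.
#
# Every phantom voxelizes a shape whose measurables are known in closed
# form, and returns the grayscale volume (foreground ~ N(100, noise_sd),
# background ~ N(20, noise_sd), clipped to [0, 255] so the standard
# threshold of 40 segments it exactly at zero noise), the exact binary
# mask, the ground truth, and any seed points / landmarks the measurement
# protocol would use.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# grayscale CT-like volume from an exact mask
phantom_grayscale <- function(mask, noise_sd = 0, seed = NULL) {
  with_seed(seed, {
    dat <- array(20, dim(mask$data))
    dat[mask$data] <- 100
    if (noise_sd > 0)
      dat <- dat + array(rnorm(length(dat), 0, noise_sd), dim(dat))
    dat[dat < 0] <- 0; dat[dat > 255] <- 255
    voxel_volume(dat, mask$spacing, mask$origin)
  })
}

# squared-radius field over a grid (broadcast sum of per-axis squares)
grid_coords <- function(n, spacing, origin) {
  lapply(1:3, function(d) origin[d] + (seq_len(n[d]) - 1) * spacing[d])
}

#' Curved-tube (helix) phantom
#'
#' A tube of radius `tube_radius` around the helix
#' `(c * theta, R cos theta, R sin theta)` for `theta` in
#' `[0, theta_max]`; axis 1 is the helix axis. Ground-truth arc length is
#' `theta_max * sqrt(R^2 + c^2)`. The seed polyline a user would place is
#' returned with `n_seeds` points on the exact centerline.
#'
#' @param helix_radius R, mm.
#' @param pitch c, mm per radian of axial advance.
#' @param theta_max swept angle, radians.
#' @param tube_radius tube radius, mm.
#' @param spacing isotropic voxel spacing, mm.
#' @param n_seeds number of centerline seed points returned.
#' @param noise_sd gray-level noise SD.
#' @param seed RNG seed.
#' @return list with `volume`, `mask`, `truth` (fields `length_mm`,
#'   `tube_radius_mm`), `seeds` (a `polyline3d`).
#' @export
phantom_curved_tube <- function(helix_radius = 3, pitch = 1,
                                theta_max = 2 * pi, tube_radius = 0.3,
                                spacing = 0.05, n_seeds = 200,
                                noise_sd = 0, seed = NULL) {
  curve <- function(th) cbind(pitch * th,
                              helix_radius * cos(th),
                              helix_radius * sin(th))
  len <- theta_max * sqrt(helix_radius^2 + pitch^2)
  phantom_tube(curve, c(0, theta_max), len, tube_radius, spacing,
               n_seeds, noise_sd, seed,
               extra_truth = list(helix_radius_mm = helix_radius,
                                  pitch_mm_per_rad = pitch))
}

#' Straight-tube phantom
#'
#' A cylinder of the given length along axis 1.
#'
#' @param length_mm tube length, mm.
#' @inheritParams phantom_curved_tube
#' @return as [phantom_curved_tube()].
#' @export
phantom_straight_tube <- function(length_mm = 10, tube_radius = 0.3,
                                  spacing = 0.05, n_seeds = 50,
                                  noise_sd = 0, seed = NULL) {
  curve <- function(t) cbind(t, 0 * t, 0 * t)
  phantom_tube(curve, c(0, length_mm), length_mm, tube_radius, spacing,
               n_seeds, noise_sd, seed)
}

# rasterise a tube around a parametric curve as a dense union of spheres
phantom_tube <- function(curve, trange, true_length, tube_radius, spacing,
                         n_seeds, noise_sd, seed, extra_truth = list()) {
  dense_n <- max(ceiling(true_length / (spacing / 2)), 50)
  tt <- seq(trange[1], trange[2], length.out = dense_n)
  pts <- curve(tt)
  margin <- tube_radius + 2 * spacing
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  n <- pmax(ceiling((hi - lo) / spacing) + 1, 3)
  m <- cpp_paint_spheres(pts, tube_radius, as.integer(n), rep(spacing, 3), lo)
  mask <- binary_mask(array(m, n), rep(spacing, 3), lo)
  seeds <- polyline3d(curve(seq(trange[1], trange[2], length.out = n_seeds)))
  list(volume = phantom_grayscale(mask, noise_sd, seed), mask = mask,
       truth = c(list(length_mm = true_length,
                      tube_radius_mm = tube_radius), extra_truth),
       seeds = seeds)
}

#' Parallel-plate trabecular lattice phantom
#'
#' Plates of the given thickness perpendicular to axis 1, repeating with
#' the given period, voxel-aligned so BV/TV = thickness/period, Tb.Th =
#' thickness, Tb.N = 1/period hold exactly on the grid.
#'
#' @param thickness plate thickness, mm (default 0.1).
#' @param period plate repeat distance, mm (default 0.4).
#' @param n_periods number of whole periods spanned along axis 1.
#' @param lateral_mm lateral extent of the block, mm.
#' @param spacing isotropic voxel spacing, mm; thickness and period must
#'   be whole multiples of it.
#' @inheritParams phantom_curved_tube
#' @return list with `volume`, `mask`, `voi` (all-true mask of the block),
#'   `truth` (`bv_tv`, `tb_th_mm`, `tb_n_per_mm`).
#' @export
phantom_plate_lattice <- function(thickness = 0.1, period = 0.4,
                                  n_periods = 3, lateral_mm = 0.6,
                                  spacing = 0.01, noise_sd = 0,
                                  seed = NULL) {
  tv <- round(thickness / spacing); pv <- round(period / spacing)
  if (abs(tv * spacing - thickness) > 1e-9 ||
      abs(pv * spacing - period) > 1e-9)
    stop_bad("thickness and period must be whole multiples of spacing")
  n1 <- n_periods * pv
  nl <- max(round(lateral_mm / spacing), 3)
  pad <- pv   # background beyond the VOI so plates have two-sided interfaces
  i <- seq_len(n1) - 1L
  inplate <- (i %% pv) < tv
  dat <- array(FALSE, c(n1 + 2 * pad, nl, nl))
  dat[pad + seq_len(n1), , ] <- inplate
  mask <- binary_mask(dat, rep(spacing, 3))
  voi_dat <- array(FALSE, dim(dat))
  voi_dat[pad + seq_len(n1), , ] <- TRUE
  voi <- binary_mask(voi_dat, rep(spacing, 3))
  list(volume = phantom_grayscale(mask, noise_sd, seed), mask = mask,
       voi = voi,
       truth = list(bv_tv = thickness / period, tb_th_mm = thickness,
                    tb_n_per_mm = 1 / period))
}

#' Growth-plate slab phantom
#'
#' A constant-thickness plate (normal along axis 1) padded with
#' background; dimensions are voxel-aligned so the voxel-count volume is
#' exact.
#'
#' @param lx,ly in-plane footprint, mm.
#' @param thickness plate thickness, mm.
#' @inheritParams phantom_plate_lattice
#' @return list with `volume`, `mask`, `truth` (`volume_mm3`,
#'   `thickness_mm`, `footprint_mm2`, `ratio_mm2`).
#' @export
phantom_gp_slab <- function(lx = 10, ly = 10, thickness = 0.2,
                            spacing = 0.05, noise_sd = 0, seed = NULL) {
  tv <- round(thickness / spacing)
  nx <- round(lx / spacing); ny <- round(ly / spacing)
  pad <- 3L
  dat <- array(FALSE, c(tv + 2 * pad, nx + 2 * pad, ny + 2 * pad))
  dat[pad + seq_len(tv), pad + seq_len(nx), pad + seq_len(ny)] <- TRUE
  mask <- binary_mask(dat, rep(spacing, 3))
  fp <- (nx * spacing) * (ny * spacing)
  vol <- fp * tv * spacing
  list(volume = phantom_grayscale(mask, noise_sd, seed), mask = mask,
       truth = list(volume_mm3 = vol, thickness_mm = tv * spacing,
                    footprint_mm2 = fp, ratio_mm2 = fp))
}

#' Growth-plate wedge phantom
#'
#' A plate whose thickness varies linearly from `t0` to `t1` across the
#' footprint (along axis 2), with a flat base. The analytic mean
#' thickness is (t0 + t1)/2 and the analytic volume is footprint times
#' mean thickness.
#'
#' @param t0,t1 thickness at the two ends of the gradient, mm.
#' @inheritParams phantom_gp_slab
#' @return list as [phantom_gp_slab()]; `truth$thickness_mm` is the mean.
#' @export
phantom_gp_wedge <- function(lx = 10, ly = 10, t0 = 0.1, t1 = 0.3,
                             spacing = 0.05, noise_sd = 0, seed = NULL) {
  nx <- round(lx / spacing); ny <- round(ly / spacing)
  n1 <- ceiling(max(t0, t1) / spacing) + 6L
  pad <- 3L
  dat <- array(FALSE, c(n1, nx + 2 * pad, ny + 2 * pad))
  ycent <- (seq_len(ny) - 0.5) * spacing
  tk <- t0 + (t1 - t0) * ycent / (ny * spacing)
  nvox <- round(tk / spacing)
  for (j in seq_len(ny))
    if (nvox[j] > 0) dat[pad + seq_len(nvox[j]), pad + seq_len(nx),
                         pad + j] <- TRUE
  mask <- binary_mask(dat, rep(spacing, 3))
  fp <- (nx * spacing) * (ny * spacing)
  list(volume = phantom_grayscale(mask, noise_sd, seed), mask = mask,
       truth = list(volume_mm3 = fp * (t0 + t1) / 2,
                    thickness_mm = (t0 + t1) / 2,
                    footprint_mm2 = fp, ratio_mm2 = fp,
                    t0_mm = t0, t1_mm = t1))
}

#' Curved growth-plate shell phantom
#'
#' A spherical-cap shell centred on axis 1 with radially measured
#' thickness growing quadratically from the centre (`t_center`) to the
#' lateral margin (`t_edge`), emulating the topography of a real growth
#' plate (thicker along the lateral sides than the centre). Ground-truth
#' volume and mean thickness are obtained by quadrature of the exact
#' closed-form integrands.
#'
#' @param R outer shell radius, mm.
#' @param t_center,t_edge radial thickness at the cap centre and rim, mm.
#' @param cap_angle_deg polar half-angle of the cap, degrees.
#' @inheritParams phantom_gp_slab
#' @return list with `volume`, `mask`, `truth` (`volume_mm3`,
#'   `thickness_center_mm`, `thickness_edge_mm`, `mean_thickness_mm`).
#' @export
phantom_gp_shell <- function(R = 5, t_center = 0.15, t_edge = 0.3,
                             cap_angle_deg = 50, spacing = 0.05,
                             noise_sd = 0, seed = NULL) {
  alpha <- cap_angle_deg * pi / 180
  tfun <- function(phi) t_center + (t_edge - t_center) * (phi / alpha)^2
  ext <- R * sin(alpha) + 3 * spacing
  lo <- c(R * cos(alpha) - max(t_center, t_edge) - 3 * spacing, -ext, -ext)
  hi <- c(R + 3 * spacing, ext, ext)
  n <- ceiling((hi - lo) / spacing) + 1
  cs <- grid_coords(n, rep(spacing, 3), lo)
  # radial distance and polar angle from the sphere centre (origin)
  y2 <- outer(cs[[2]]^2, cs[[3]]^2, `+`)
  dat <- array(FALSE, n)
  for (i in seq_len(n[1])) {
    r <- sqrt(cs[[1]][i]^2 + y2)
    phi <- acos(pmin(pmax(cs[[1]][i] / pmax(r, 1e-12), -1), 1))
    tk <- tfun(pmin(phi, alpha))
    dat[i, , ] <- phi <= alpha & r <= R & r >= R - tk
  }
  mask <- binary_mask(array(dat, n), rep(spacing, 3), lo)
  # exact quadrature over the closed-form integrand
  volfun <- function(phi) 2 * pi * sin(phi) * (R^3 - (R - tfun(phi))^3) / 3
  vol <- stats::integrate(volfun, 0, alpha, rel.tol = 1e-10)$value
  # outer-surface-area-weighted mean radial thickness
  wfun <- function(phi) 2 * pi * R^2 * sin(phi)
  mth <- stats::integrate(function(p) tfun(p) * wfun(p), 0, alpha,
                          rel.tol = 1e-10)$value /
    stats::integrate(wfun, 0, alpha, rel.tol = 1e-10)$value
  list(volume = phantom_grayscale(mask, noise_sd, seed), mask = mask,
       truth = list(volume_mm3 = vol, thickness_center_mm = t_center,
                    thickness_edge_mm = t_edge, mean_thickness_mm = mth,
                    cap_angle_rad = alpha, outer_radius_mm = R))
}

#' Hollow spherical-shell skull phantom
#'
#' A shell of outer radius `R` and inner radius `r`, optionally with a
#' conical aperture (foramen) cut around the -axis1 pole. Ground-truth
#' bone volume is the closed-form shell (sector) volume.
#'
#' @param R,r outer and inner radii, mm.
#' @param aperture_rim_radius rim radius of the aperture on the outer
#'   sphere, mm (0 = closed shell).
#' @inheritParams phantom_gp_slab
#' @return list with `volume`, `mask`, `truth` (`volume_mm3`, and the rim
#'   geometry when an aperture is cut).
#' @export
phantom_skull_shell <- function(R = 5, r = 4.8, aperture_rim_radius = 0,
                                spacing = 0.04, noise_sd = 0, seed = NULL) {
  stopifnot(r < R)
  ext <- R + 3 * spacing
  lo <- rep(-ext, 3)
  n <- rep(ceiling(2 * ext / spacing) + 1, 3)
  cs <- grid_coords(n, rep(spacing, 3), lo)
  y2 <- outer(cs[[2]]^2, cs[[3]]^2, `+`)
  beta <- if (aperture_rim_radius > 0) asin(aperture_rim_radius / R) else 0
  dat <- array(FALSE, n)
  for (i in seq_len(n[1])) {
    r2 <- cs[[1]][i]^2 + y2
    keep <- r2 <= R^2 & r2 >= r^2
    if (beta > 0) {
      # cut the cone around the -axis1 pole
      cosphi <- cs[[1]][i] / sqrt(pmax(r2, 1e-12))
      keep <- keep & cosphi > -cos(beta)
    }
    dat[i, , ] <- keep
  }
  mask <- binary_mask(array(dat, n), rep(spacing, 3), lo)
  frac <- (1 + cos(beta)) / 2   # solid-angle fraction kept
  vol <- 4 / 3 * pi * (R^3 - r^3) * frac
  truth <- list(volume_mm3 = vol)
  if (beta > 0)
    truth <- c(truth, list(rim_radius_mm = aperture_rim_radius,
                           rim_circumference_mm = 2 * pi * aperture_rim_radius))
  list(volume = phantom_grayscale(mask, noise_sd, seed), mask = mask,
       truth = truth)
}

#' Spherical skull surface with exact circular apertures (mesh)
#'
#' A UV-parameterised sphere surface with polar caps removed at both
#' poles, leaving two exactly circular rims whose radii are given; the
#' larger rim models the foramen magnum. Rim vertices lie exactly on the
#' rim circles, so rim length converges to the circle circumference with
#' mesh resolution.
#'
#' @param R sphere radius, mm.
#' @param rim_radius rim radius of the principal (foramen) aperture, mm.
#' @param rim_radius2 rim radius of the secondary aperture at the
#'   opposite pole, mm (must be smaller; 0 for a tiny numerical cap).
#' @param n_theta,n_phi mesh resolution along polar and azimuthal angles.
#' @return list with `mesh` (a `surface_mesh`) and `truth`
#'   (`circumference_mm`, `d_t_mm`, `d_s_mm`, `area_mm2` of the principal
#'   rim, from the exact circle).
#' @export
mesh_skull_aperture <- function(R = 5, rim_radius = 1, rim_radius2 = 0.4,
                                n_theta = 60, n_phi = 200) {
  stopifnot(rim_radius < R, rim_radius2 < rim_radius)
  th1 <- pi - asin(rim_radius / R)    # principal aperture at -axis1 pole
  th0 <- asin(max(rim_radius2, 1e-3) / R)
  th <- seq(th0, th1, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  vid <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  verts <- matrix(0, n_theta * n_phi, 3)
  for (i in seq_len(n_theta)) {
    verts[vid(i, seq_len(n_phi)), ] <-
      cbind(R * cos(th[i]), R * sin(th[i]) * cos(ph), R * sin(th[i]) * sin(ph))
  }
  faces <- matrix(0L, 2 * (n_theta - 1) * n_phi, 3)
  k <- 0L
  for (i in seq_len(n_theta - 1)) for (j in seq_len(n_phi)) {
    faces[k + 1L, ] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1))
    faces[k + 2L, ] <- c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1))
    k <- k + 2L
  }
  a <- rim_radius
  list(mesh = surface_mesh(verts, faces),
       truth = list(circumference_mm = 2 * pi * a, d_t_mm = 2 * a,
                    d_s_mm = 2 * a, area_mm2 = pi * a^2))
}

#' Elliptical aperture mesh
#'
#' An elliptical tube closed at the far end by a fan, leaving one exactly
#' elliptical planar boundary loop with the given transverse and sagittal
#' diameters; used to validate the 1/4 pi Dt Ds area formula and the rim
#' circumference against Ramanujan's perimeter approximation.
#'
#' @param d_t,d_s transverse and sagittal rim diameters, mm (extents
#'   along axes 2 and 3).
#' @param depth tube depth along axis 1, mm.
#' @param n_phi rim resolution.
#' @return list with `mesh` and `truth` (`d_t_mm`, `d_s_mm`, `area_mm2`,
#'   `circumference_ramanujan_mm`).
#' @export
mesh_elliptical_aperture <- function(d_t = 4, d_s = 2, depth = 2,
                                     n_phi = 400) {
  a <- d_t / 2; b <- d_s / 2
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  rim <- cbind(0, a * cos(ph), b * sin(ph))
  far <- cbind(depth, a * cos(ph), b * sin(ph))
  apex <- c(depth, 0, 0)
  verts <- rbind(rim, far, apex)
  nxt <- c(seq_len(n_phi)[-1], 1L)
  side <- rbind(cbind(seq_len(n_phi), n_phi + seq_len(n_phi), n_phi + nxt),
                cbind(seq_len(n_phi), n_phi + nxt, nxt))
  cap <- cbind(n_phi + seq_len(n_phi), 2L * n_phi + 1L, n_phi + nxt)
  h <- ((a - b) / (a + b))^2
  peri <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  list(mesh = surface_mesh(verts, rbind(side, cap)),
       truth = list(d_t_mm = d_t, d_s_mm = d_s, area_mm2 = pi * a * b,
                    circumference_ramanujan_mm = peri))
}

#' Ellipsoidal brain phantom (coronal slice stack)
#'
#' Segmented coronal slices of an ellipsoid with semi-axes (a, b, c),
#' sliced along c at the given thickness; ground-truth volume is
#' 4/3 pi a b c.
#'
#' @param a,b in-plane semi-axes, mm.
#' @param c_ax semi-axis along the slicing direction, mm.
#' @param slice_thickness_mm coronal slice thickness (default 0.5).
#' @param in_plane in-plane pixel spacing, mm.
#' @return list with `slice_masks` (list of logical matrices),
#'   `slice_thickness_mm`, `in_plane_spacing`, `truth` (`volume_mm3`).
#' @export
phantom_ellipsoid_brain <- function(a = 8, b = 6, c_ax = 5,
                                    slice_thickness_mm = 0.5,
                                    in_plane = 0.05) {
  nsl <- ceiling(2 * c_ax / slice_thickness_mm)
  zc <- -c_ax + (seq_len(nsl) - 0.5) * slice_thickness_mm
  nx <- ceiling(2 * (a + 2 * in_plane) / in_plane)
  ny <- ceiling(2 * (b + 2 * in_plane) / in_plane)
  xs <- (seq_len(nx) - (nx + 1) / 2) * in_plane
  ys <- (seq_len(ny) - (ny + 1) / 2) * in_plane
  slices <- lapply(zc, function(z) {
    s2 <- 1 - (z / c_ax)^2
    if (s2 <= 0) return(matrix(FALSE, nx, ny))
    outer(xs^2 / (a^2 * s2), ys^2 / (b^2 * s2), `+`) <= 1
  })
  list(slice_masks = slices, slice_thickness_mm = slice_thickness_mm,
       in_plane_spacing = c(in_plane, in_plane),
       truth = list(volume_mm3 = 4 / 3 * pi * a * b * c_ax))
}

#' Curved vertebral-column phantom
#'
#' A circular-arc "spinal canal" tube of the given chord and sagitta in
#' the lateral (axis1-axis2) plane, with the dorsal profile polyline and
#' the canal seed points sampled on the exact arc. Ground truth: KI =
#' chord/sagitta and the analytic arc length.
#'
#' @param chord straight distance between the arc endpoints, mm.
#' @param sagitta maximal perpendicular deviation of the arc from the
#'   chord, mm.
#' @param tube_radius canal tube radius, mm.
#' @param n_profile points in the dorsal profile polyline.
#' @inheritParams phantom_curved_tube
#' @return list with `volume`, `mask`, `profile` (2D `polyline3d`),
#'   `seeds` (3D canal seeds), `truth` (`ki`, `arc_length_mm`,
#'   `chord_mm`, `sagitta_mm`).
#' @export
phantom_vertebral_column <- function(chord = 20, sagitta = 10,
                                     tube_radius = 0.5, spacing = 0.1,
                                     n_profile = 200, noise_sd = 0,
                                     seed = NULL) {
  L <- chord / 2
  rho <- (L^2 + sagitta^2) / (2 * sagitta)
  half_ang <- asin(pmin(L / rho, 1))
  if (sagitta > L) half_ang <- pi - half_ang   # major arc
  arc_len <- 2 * rho * half_ang
  # arc in the (axis1, axis2) plane; chord along axis 1, bulge along axis 2
  ang <- seq(-half_ang, half_ang, length.out = n_profile)
  arc2d <- cbind(rho * sin(ang), rho * cos(ang) - (rho - sagitta))
  profile <- polyline3d(arc2d)
  curve <- function(t) {
    th <- -half_ang + (t + half_ang) - 0  # identity on angle parameter
    cbind(rho * sin(th), rho * cos(th) - (rho - sagitta), 0 * th)
  }
  tube <- phantom_tube(function(th) curve(th), c(-half_ang, half_ang),
                       arc_len, tube_radius, spacing, 100, noise_sd, seed)
  list(volume = tube$volume, mask = tube$mask, profile = profile,
       seeds = tube$seeds,
       truth = list(ki = chord / sagitta, arc_length_mm = arc_len,
                    chord_mm = chord, sagitta_mm = sagitta))
}

#' Generate a phantom from a declarative spec
#'
#' Dispatcher over the individual `phantom_*` / `mesh_*` generators.
#'
#' @param kind one of `"curved_tube"`, `"straight_tube"`,
#'   `"plate_lattice"`, `"gp_slab"`, `"gp_wedge"`, `"gp_shell"`,
#'   `"skull_shell"`, `"skull_aperture_mesh"`, `"elliptical_aperture"`,
#'   `"ellipsoid_brain"`, `"vertebral_column"`.
#' @param ... parameters of the corresponding generator.
#' @return the generator's result list (always containing `truth`).
#' @export
generate_phantom <- function(kind, ...) {
  gen <- switch(kind,
                curved_tube = phantom_curved_tube,
                straight_tube = phantom_straight_tube,
                plate_lattice = phantom_plate_lattice,
                gp_slab = phantom_gp_slab,
                gp_wedge = phantom_gp_wedge,
                gp_shell = phantom_gp_shell,
                skull_shell = phantom_skull_shell,
                skull_aperture_mesh = mesh_skull_aperture,
                elliptical_aperture = mesh_elliptical_aperture,
                ellipsoid_brain = phantom_ellipsoid_brain,
                vertebral_column = phantom_vertebral_column,
                stop_bad("unknown phantom kind: ", kind))
  gen(...)
}

#' Synthetic two-genotype, two-age study table
#'
#' Emulates the cross-sectional design of a 3-/6-week WT-vs-Ach study:
#' independent animals per age group, Gaussian measurement values, and
#' per-measurement effects specified in SD units at each age (Ach mean =
#' WT mean + effect * SD).
#'
#' @param n_per_group animals per genotype per age (>= 2).
#' @param effects named list: measurement_name -> numeric length-2 c(
#'   effect at 3 weeks, effect at 6 weeks) in SD units.
#' @param baseline named list or single number: WT mean per measurement.
#' @param sd_value within-group SD (measurement units).
#' @param ages age groups in weeks.
#' @param seed RNG seed.
#' @return a `study_table`.
#' @export
generate_study <- function(n_per_group = 10,
                           effects = list(gp_volume = c(-2, 0)),
                           baseline = 10, sd_value = 1,
                           ages = c(3, 6), seed = NULL) {
  if (n_per_group < 2) stop_bad("n_per_group must be >= 2")
  if (length(effects) == 0 || is.null(names(effects)) ||
      any(names(effects) == ""))
    stop_bad("`effects` must be a named list of length-", length(ages),
             " numeric vectors")
  with_seed(seed, {
    rows <- list()
    aid <- 0L
    for (age_i in seq_along(ages)) {
      for (g in c("WT", "Ach")) {
        for (k in seq_len(n_per_group)) {
          aid <- aid + 1L
          id <- sprintf("%s_%dwk_%02d", g, ages[age_i], k)
          sex <- if (k %% 2 == 0) "F" else "M"
          for (mname in names(effects)) {
            eff <- effects[[mname]]
            if (length(eff) != length(ages))
              stop_bad("effect for ", mname, " must have one entry per age")
            mu <- if (is.list(baseline)) baseline[[mname]] else baseline
            shift <- if (g == "Ach") eff[age_i] * sd_value else 0
            rows[[length(rows) + 1L]] <- data.frame(
              animal_id = id, genotype = g, sex = sex,
              age_weeks = ages[age_i], measurement_name = mname,
              value = rnorm(1, mu + shift, sd_value),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    study_table(do.call(rbind, rows))
  })
}
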