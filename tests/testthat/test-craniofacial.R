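# Skull volume, brain volume, foramen morphometry.

test_that("skull volume matches analytic shells and is antitone in level", {
  ph <- phantom_skull_shell(R = 5, r = 4.8, spacing = 0.04)
  expect_equal(skull_volume(ph$volume), 4 / 3 * pi * (5^3 - 4.8^3),
               tolerance = 0.02)
  v40 <- skull_volume(ph$volume, 40)
  v90 <- skull_volume(ph$volume, 90)
  expect_gte(v40, v90)
  expect_error(skull_volume(ph$volume, level = 300), "empty segmentation")
  # solid 1 mm cube voxel-aligned: exact
  cube <- binary_mask(array(TRUE, c(10, 10, 10)), rep(0.1, 3))
  pad <- array(20, c(14, 14, 14)); pad[3:12, 3:12, 3:12] <- 100
  vol <- voxel_volume(pad, rep(0.1, 3))
  expect_equal(skull_volume(vol), 1, tolerance = 1e-12)
})

test_that("brain volume integrates coronal slice areas", {
  ph <- phantom_ellipsoid_brain(a = 8, b = 6, c_ax = 5,
                                slice_thickness_mm = 0.5)
  v <- brain_volume(ph$slice_masks, ph$slice_thickness_mm,
                    ph$in_plane_spacing)
  expect_equal(v, 4 / 3 * pi * 8 * 6 * 5, tolerance = 0.02)
  # single 1 mm^2 slice, 0.5 mm thick
  sl <- list(matrix(TRUE, 10, 10))
  expect_equal(brain_volume(sl, 0.5, c(0.1, 0.1)), 0.5)
  expect_error(brain_volume(list(matrix(FALSE, 4, 4)), 0.5, c(0.1, 0.1)),
               "empty")
  expect_error(brain_volume(list(matrix(TRUE, 4, 4), matrix(TRUE, 5, 4)),
                            0.5, c(0.1, 0.1)), "one shape")
})

test_that("foramen rim is the longest boundary loop of the skull surface", {
  # two apertures: rims of radius 1 and 0.5 mm; the larger must win
  ph <- mesh_skull_aperture(R = 5, rim_radius = 1, rim_radius2 = 0.5)
  loop <- foramen_boundary(ph$mesh)
  expect_true(loop$closed)
  expect_equal(polyline_length(loop), 2 * pi, tolerance = 0.02)
  # watertight mesh is rejected
  expect_error(foramen_boundary(unit_cube_mesh()), "watertight")
})

test_that("foramen metrics follow the quarter-pi ellipse formula", {
  # circular rim radius 1 -> Dt = Ds = 2, area = pi
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  circ <- polyline3d(cbind(0, cos(th), sin(th)), closed = TRUE)
  m <- foramen_metrics(circ)
  expect_equal(m$d_t_mm, 2, tolerance = 1e-3)
  expect_equal(m$area_mm2, pi, tolerance = 1e-2)
  # ellipse Dt = 4, Ds = 2: area 2*pi exactly, circumference ~ Ramanujan
  ell <- mesh_elliptical_aperture(d_t = 4, d_s = 2)
  me <- foramen_metrics(foramen_boundary(ell$mesh))
  expect_equal(me$area_mm2, 2 * pi, tolerance = 1e-9)
  expect_equal(me$circumference_mm, ell$truth$circumference_ramanujan_mm,
               tolerance = 0.02)
  # degenerate collinear loop
  bad <- polyline3d(cbind(0, c(0, 1, 2, 1), 0), closed = TRUE)
  expect_error(foramen_metrics(bad), "degenerate")
  expect_error(foramen_metrics(circ, transverse_axis = c(0, 1, 0),
                               sagittal_axis = c(0, 1, 1)), "orthogonal")
})

test_that("a saddle-warped rim is longer than its planar projection", {
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  warp <- polyline3d(cbind(0.4 * cos(2 * th), cos(th), sin(th)),
                     closed = TRUE)
  flat <- polyline3d(cbind(0, cos(th), sin(th)), closed = TRUE)
  expect_gt(polyline_length(warp), polyline_length(flat))
})
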