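# Core types, coordinate maps, and file round trips.

test_that("voxel grid geometry and index/world maps are exact inverses", {
  vol <- voxel_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                      spacing = c(0.0086, 0.0086, 0.0172),
                      origin = c(-1, 2, 0.5))
  ijk <- as.matrix(expand.grid(1:4, 1:5, 1:6))
  xyz <- world_from_index(vol, ijk)
  back <- index_from_world(vol, xyz)
  expect_lt(max(abs(back - ijk)), 1e-12)
  expect_error(voxel_volume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(voxel_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
})

test_that("mask volume equals voxel count times voxel volume exactly", {
  m <- binary_mask(array(TRUE, c(3, 4, 5)), spacing = c(0.1, 0.2, 0.05))
  expect_identical(volume_mm3(m), 3 * 4 * 5 * 0.1 * 0.2 * 0.05)
  m$data[1, 1, 1] <- FALSE
  expect_equal(volume_mm3(m), 59 * 0.001)
})

test_that("polyline length sums segments and respects the closed flag", {
  p <- polyline3d(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(polyline_length(p), 10)
  tri <- polyline3d(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)), closed = TRUE)
  expect_equal(polyline_length(tri), 3 + 4 + 5)
  expect_gte(polyline_length(polyline3d(rbind(c(0, 0, 0), c(1, 1, 0),
                                              c(2, 0, 0)))), 2)
  expect_error(polyline3d(rbind(c(0, 0, 0))), "2 points")
  expect_error(polyline3d(rbind(c(0, 0, NA), c(1, 1, 1))), "finite")
})

test_that("NIfTI volumes round-trip data and spacing", {
  vol <- voxel_volume(array(runif(4^3, 0, 255), c(4, 4, 4)),
                      spacing = c(0.0086, 0.0086, 0.0086))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-12)
  # NIfTI-1 stores pixdim in single precision
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
})

test_that("TIFF stacks require explicit spacing", {
  pages <- lapply(1:3, function(k) matrix(runif(12), 3, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  expect_error(read_volume(path), "spacing")
  vol <- read_volume(path, spacing = c(0.0086, 0.0086, 0.0086))
  expect_equal(vol$spacing, rep(0.0086, 3))
  expect_equal(dim(vol$data), c(3L, 3L, 4L))
  expect_equal(vol$data[2, , ], pages[[2]], tolerance = 1e-6)
})

test_that("meshes round-trip through ASCII STL and PLY", {
  cube <- unit_cube_mesh()
  for (ext in c(".stl", ".ply")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(cube, path)
    back <- read_mesh(path)
    expect_equal(nrow(back$vertices), 8L)
    expect_equal(nrow(back$faces), 12L)
    expect_equal(mesh_area(back), 6, tolerance = 1e-9)
  }
  # curved mesh: total area preserved to 1e-6 relative
  sph <- mesh_skull_aperture(n_theta = 20, n_phi = 40)$mesh
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(sph, path)
  expect_equal(mesh_area(read_mesh(path)), mesh_area(sph),
               tolerance = 1e-6)
  expect_error(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)), "at least")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 4))), "out of range")
})

test_that("study tables validate keys and round-trip through CSV", {
  df <- data.frame(animal_id = c("a", "b"), genotype = c("WT", "Ach"),
                   sex = c("M", "F"), age_weeks = 3,
                   measurement_name = "tibia_length",
                   value = c(17.123456789012, 15.5))
  st <- study_table(df)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(st, path)
  back <- read_results(path)
  expect_equal(back$value, st$value, tolerance = 1e-12)
  expect_identical(back$animal_id, st$animal_id)
  bad <- df; bad$value[1] <- NaN
  expect_error(study_table(bad), "finite")
  dup <- rbind(df, df[1, ])
  expect_error(study_table(dup), "duplicate")
})

test_that("a full synthetic study has one row per animal-measurement", {
  st <- generate_study(n_per_group = 14,
                       effects = list(body_length = c(-2, -1),
                                      brain_volume = c(-1, -1)),
                       seed = 11)
  # 14 per genotype per age x 2 genotypes x 2 ages = 56 animals
  expect_equal(length(unique(st$animal_id)), 56L)
  expect_equal(nrow(st), 56L * 2L)
})

test_that("landmark sets enforce labels and dimensionality", {
  lm <- landmark_set(list(nasal_tip = c(0, 0), first_caudal_base = c(85, 0)))
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$nasal_tip, c(0, 0))
  expect_error(landmark_set(list(a = c(0, 0), b = c(1, 2, 3))), "2D or all 3D")
  expect_error(landmark_set(list(c(0, 0))), "labels")
})
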