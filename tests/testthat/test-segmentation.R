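# Thresholding, component cleanup, VOI construction.

test_that("threshold is inclusive at the level and antitone in level", {
  vol <- voxel_volume(array(c(30, 40, 50, 10, 200, 40, 39.999, 40.0001),
                            c(2, 2, 2)), rep(0.01, 3))
  m40 <- threshold_mask(vol, 40)
  expect_identical(as.vector(m40$data)[1:3], c(FALSE, TRUE, TRUE))
  expect_true(all(threshold_mask(vol, min(vol$data) - 1)$data))
  # monotone sweep over gray levels 30..50 on a noisy phantom
  ph <- phantom_plate_lattice(spacing = 0.02, lateral_mm = 0.2,
                              noise_sd = 10, seed = 3)
  prev <- threshold_mask(ph$volume, 30)
  for (lev in c(35, 40, 45, 50)) {
    cur <- threshold_mask(ph$volume, lev)
    expect_true(all(prev$data | !cur$data))  # cur subset of prev
    prev <- cur
  }
  expect_error(threshold_mask(vol, NaN), "finite")
})

test_that("largest_component keeps the biggest blob with a fixed tie-break", {
  d <- array(FALSE, c(10, 10, 10))
  d[2:5, 2:6, 2:6] <- TRUE            # 100 voxels
  d[8:9, 8:9, 8:9] <- TRUE            # 8 voxels (disjoint, diag gap > 1)
  m <- binary_mask(d, rep(0.1, 3))
  keep <- largest_component(m)
  expect_equal(sum(keep$data), 100L)
  # identity on a single blob
  single <- binary_mask(keep$data, rep(0.1, 3))
  expect_identical(largest_component(single)$data, single$data)
  # equal-size tie: the component containing the smallest linear index wins
  d2 <- array(FALSE, c(10, 10, 10))
  d2[8:9, 8:9, 8:9] <- TRUE           # later in scan order
  d2[1:2, 1:2, 1:2] <- TRUE           # earlier, same 8 voxels
  tie <- largest_component(binary_mask(d2, rep(0.1, 3)))
  expect_true(tie$data[1, 1, 1])
  expect_false(tie$data[8, 8, 8])
  # brute-force confirmation of the winner's minimal index
  expect_equal(min(which(tie$data)), min(which(d2)))
  expect_error(largest_component(binary_mask(array(FALSE, c(2, 2, 2)),
                                             rep(1, 3))), "empty")
})

test_that("VOI slice arithmetic follows the mm protocol on the 8.6 um grid", {
  # 0.1 mm / 0.0086 mm -> 12 slices, 0.5 mm -> 58 slices
  n1 <- 120
  d <- array(TRUE, c(n1, 4, 4))
  m <- binary_mask(d, c(0.0086, 0.0086, 0.0086))
  spec <- voi_spec(reference_slice = 10, offset_mm = 0.1, extent_mm = 0.5)
  voi <- build_voi(m, spec)
  support <- which(apply(voi$data, 1, any))
  expect_equal(min(support), 10 + 12)
  expect_equal(length(support), 58)
  # offset 0 starts at the reference slice
  voi0 <- build_voi(m, voi_spec(10, offset_mm = 0, extent_mm = 0.5))
  expect_equal(min(which(apply(voi0$data, 1, any))), 10)
  # degenerate extent
  expect_error(build_voi(m, voi_spec(10, extent_mm = 0.004)), "slice spacing")
  # VOI exits volume
  expect_error(build_voi(m, voi_spec(100, offset_mm = 0.1, extent_mm = 0.5)),
               "exits")
  # output is a subset of the input mask with exactly the computed width
  d2 <- d; d2[, 1:2, ] <- FALSE
  m2 <- binary_mask(d2, c(0.0086, 0.0086, 0.0086))
  v2 <- build_voi(m2, spec)
  expect_true(all(!v2$data | m2$data))
})

test_that("voi_spec validates its geometry", {
  expect_error(voi_spec(5, offset_mm = -0.1), "offset")
  expect_error(voi_spec(5, extent_mm = 0), "extent")
  expect_error(voi_spec(5, direction = 2), "direction")
})
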