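# Growth-plate volume, two-surface thickness, and the area surrogate.

test_that("plate volume is exact voxel counting", {
  ph <- phantom_gp_slab(lx = 10, ly = 10, thickness = 0.2, spacing = 0.05)
  expect_equal(gp_volume(ph$mask), 20)
  one <- binary_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)),
                     rep(0.0086, 3))
  expect_equal(gp_volume(one), 0.0086^3)
  expect_error(gp_volume(binary_mask(array(FALSE, c(2, 2, 2)), rep(1, 3))),
               "empty")
})

test_that("slab thickness, histogram and ratio match the constant plate", {
  ph <- phantom_gp_slab(lx = 6, ly = 6, thickness = 0.2, spacing = 0.05)
  res <- growthplate_metrics(ph$mask)
  expect_equal(res$thickness_mean_mm, 0.2, tolerance = 0.05 / 0.2)
  expect_equal(res$ratio_mm2, res$volume_mm3 / res$thickness_mean_mm)
  # histogram mass concentrated around the single thickness
  h <- res$thickness$histogram
  modal <- sum(h$counts[abs(h$mids - 0.2) < 0.03]) / sum(h$counts)
  expect_gt(modal, 0.9)
  # two near-parallel sheets of equal area within 2%
  pa <- mesh_area(res$surfaces$proximal)
  da <- mesh_area(res$surfaces$distal)
  expect_equal(pa, da, tolerance = 0.02)
})

test_that("thickness is symmetric under sheet swap within 2%", {
  ph <- phantom_gp_slab(lx = 3, ly = 3, thickness = 0.2, spacing = 0.05)
  sh <- split_surfaces(ph$mask)
  t1 <- gp_thickness(sh$proximal, sh$distal)$mean_mm
  t2 <- gp_thickness(sh$distal, sh$proximal)$mean_mm
  expect_equal(t1, t2, tolerance = 0.02)
})

test_that("wedge recovers the linear gradient and the footprint area", {
  ph <- phantom_gp_wedge(lx = 6, ly = 6, t0 = 0.1, t1 = 0.3, spacing = 0.05)
  res <- growthplate_metrics(ph$mask)
  expect_equal(res$thickness_mean_mm, 0.2, tolerance = 0.05 / 0.2)
  expect_equal(res$ratio_mm2, ph$truth$footprint_mm2, tolerance = 0.05)
  # the topographic map reproduces the gradient monotonically along axis 3
  m <- res$thickness$map$thickness_mm
  prof <- colMeans(m, na.rm = TRUE)
  prof <- prof[!is.na(prof)]
  inner <- prof[3:(length(prof) - 2)]    # rim bins are roll-off
  fit <- coef(lm(inner ~ seq_along(inner)))[2]
  expect_gt(fit, 0)
  expect_gt(max(inner), 0.25)
  expect_lt(min(inner), 0.15)
})

test_that("curved shell: volume matches quadrature and map peaks laterally", {
  ph <- phantom_gp_shell()
  res <- growthplate_metrics(ph$mask)
  expect_equal(res$volume_mm3, ph$truth$volume_mm3, tolerance = 0.01)
  expect_gt(mesh_area(res$surfaces$proximal),
            mesh_area(res$surfaces$distal))
  # thicker along the lateral margin than the centre
  m <- res$thickness$map$thickness_mm
  n1 <- nrow(m); n2 <- ncol(m)
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  rad <- sqrt(outer((seq_len(n1) - c1)^2, (seq_len(n2) - c2)^2, `+`))
  centre <- mean(m[rad < max(rad, na.rm = TRUE) * 0.25], na.rm = TRUE)
  margin <- mean(m[!is.na(m) & rad > max(rad[!is.na(m)]) * 0.8], na.rm = TRUE)
  expect_gt(margin, centre)
})

test_that("degenerate inputs are rejected", {
  expect_error(split_surfaces(sphere_mask(0.2, 0.02)), "plate orientation")
  expect_error(gp_ratio(20, 0), "> 0")
  expect_equal(gp_ratio(0, 0.2), 0)
  expect_equal(gp_ratio(20, 0.2), 100)
})
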