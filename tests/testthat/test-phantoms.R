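# Phantom generators: determinism, gray-level model, and full-pipeline
# parameter recovery against the attached ground truth.

test_that("phantoms are bit-identical under a fixed seed", {
  a <- phantom_plate_lattice(spacing = 0.02, lateral_mm = 0.2,
                             noise_sd = 10, seed = 123)
  b <- phantom_plate_lattice(spacing = 0.02, lateral_mm = 0.2,
                             noise_sd = 10, seed = 123)
  expect_identical(a$volume$data, b$volume$data)
  c <- phantom_plate_lattice(spacing = 0.02, lateral_mm = 0.2,
                             noise_sd = 10, seed = 124)
  expect_false(identical(c$volume$data, b$volume$data))
})

test_that("the gray-level model thresholds exactly at 40 when noise-free", {
  ph <- phantom_gp_slab(lx = 2, ly = 2, thickness = 0.2, spacing = 0.05)
  seg <- threshold_mask(ph$volume, 40)
  expect_identical(seg$data, ph$mask$data)
  expect_true(all(ph$volume$data %in% c(20, 100)))
})

test_that("noise-free phantoms recover ground truth through the pipeline", {
  # curved length from phantom seed points
  hx <- phantom_curved_tube()
  expect_equal(curved_length(hx$seeds), hx$truth$length_mm,
               tolerance = 0.02)
  # trabecular triple through threshold 40
  pl <- phantom_plate_lattice(n_periods = 2, lateral_mm = 0.3,
                              spacing = 0.01)
  tr <- trabecular_metrics(threshold_mask(pl$volume, 40), voi = pl$voi)
  expect_equal(tr$bv_tv, pl$truth$bv_tv, tolerance = 0.02)
  expect_equal(tr$tb_th, pl$truth$tb_th_mm, tolerance = 0.01 / 0.1)
  expect_equal(tr$tb_n, pl$truth$tb_n_per_mm, tolerance = 0.1)
  # growth-plate slab volume via the segmented volume
  gs <- phantom_gp_slab(lx = 4, ly = 4, thickness = 0.2, spacing = 0.05)
  seg <- largest_component(threshold_mask(gs$volume, 40))
  expect_equal(gp_volume(seg), gs$truth$volume_mm3, tolerance = 0.02)
  # skull shell volume
  sk <- phantom_skull_shell(spacing = 0.05)
  expect_equal(skull_volume(sk$volume, 40), sk$truth$volume_mm3,
               tolerance = 0.02)
  # vertebral canal
  vc <- phantom_vertebral_column(chord = 12, sagitta = 3)
  expect_equal(kyphosis_index(vc$profile), vc$truth$ki, tolerance = 0.01)
  expect_equal(curved_length(vc$seeds), vc$truth$arc_length_mm,
               tolerance = 0.01)
})

test_that("recovery degrades gracefully under gray-level noise", {
  pl0 <- phantom_plate_lattice(thickness = 0.15, period = 0.45,
                               n_periods = 2, lateral_mm = 0.45,
                               spacing = 0.05)
  pl <- phantom_plate_lattice(thickness = 0.15, period = 0.45,
                              n_periods = 2, lateral_mm = 0.45,
                              spacing = 0.05, noise_sd = 15, seed = 6)
  tr0 <- trabecular_metrics(threshold_mask(pl0$volume, 40), voi = pl0$voi)
  tr <- trabecular_metrics(threshold_mask(pl$volume, 40), voi = pl$voi)
  # noise-free within half a voxel of plate thickness; noisy within twice
  half_vox_bvtv <- 0.5 * 0.05 / 0.45
  expect_lt(abs(tr0$bv_tv - pl0$truth$bv_tv), half_vox_bvtv)
  expect_lt(abs(tr$bv_tv - pl$truth$bv_tv), 2 * half_vox_bvtv)
  expect_lt(abs(tr0$tb_th - pl0$truth$tb_th_mm), 0.05)
  expect_lt(abs(tr$tb_th - pl$truth$tb_th_mm), 0.1)
})

test_that("generate_study honours effects, ages and reproducibility", {
  st <- generate_study(n_per_group = 10,
                       effects = list(m = c(-2, 0)), seed = 5)
  st2 <- generate_study(n_per_group = 10,
                        effects = list(m = c(-2, 0)), seed = 5)
  expect_identical(st, st2)
  m3 <- with(st[st$age_weeks == 3, ], tapply(value, genotype, mean))
  expect_lt(m3[["Ach"]], m3[["WT"]])   # -2 SD shift at 3 weeks
  expect_error(generate_study(n_per_group = 1,
                              effects = list(m = c(0, 0))), "n_per_group")
  expect_error(generate_study(effects = list(0.5)), "named")
  expect_error(generate_study(effects = list(m = 1)), "per age")
})

test_that("the phantom dispatcher routes kinds and rejects unknowns", {
  ph <- generate_phantom("gp_slab", lx = 2, ly = 2, thickness = 0.2,
                         spacing = 0.05)
  expect_equal(ph$truth$ratio_mm2, 4)
  expect_error(generate_phantom("femur"), "unknown phantom kind")
})
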