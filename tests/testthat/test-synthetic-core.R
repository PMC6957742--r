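test_that("a scene without burrows yields empty labels and truth table", {
  spec <- small_scene(list(), seed = 4, nz = 20L)
  sc <- generate_core(spec)
  expect_true(all(sc$truth$label_volume$labels == 0L))
  expect_equal(nrow(sc$truth$table), 0L)
  expect_identical(dim(sc$volume$data), c(96L, 56L, 20L))
})

test_that("generation is bit-for-bit reproducible for a fixed seed", {
  spec <- small_scene(list(small_tube(45), small_tube(80, azimuth_deg = 90)),
                      seed = 11, nz = 40L)
  a <- generate_core(spec)
  b <- generate_core(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$label_volume$labels, b$truth$label_volume$labels)
  expect_equal(a$truth$table, b$truth$table)
})

test_that("disjoint tubes get labels in listed order with conserved volumes", {
  burrows <- ichnoCT:::with_seed(21, ichnoCT:::place_disjoint_tubes(
    3, c(2, 3), c(10, 15), c(0, 90), c(8, 8),
    c(96L, 56L, 80L), SMALL_SP, 14, 2, 1.5))
  sc <- generate_core(small_scene(burrows, seed = 21))
  labs <- sc$truth$label_volume$labels
  expect_setequal(unique(as.vector(labs[labs > 0])), 1:3)
  expect_equal(nrow(sc$truth$table), 3L)
  # truth-volume conservation against brute-force voxel counting
  counts <- tabulate(labs, nbins = 3)
  expect_identical(sc$truth$table$voxel_count, counts)
  expect_equal(sc$truth$table$volume_mm3, counts * prod(SMALL_SP))
})

test_that("rasterised cylinder volume matches the analytic cylinder", {
  # 2 mm diameter, 50 mm vertical tube on a 0.5 mm isotropic grid
  sp <- c(0.5, 0.5, 0.5)
  spec <- scene_spec(c(72L, 44L, 120L), sp, core_radius_mm = 14, rim_mm = 2,
                     liner_thickness_mm = 1.5, seed = 3,
                     burrows = list(burrow_spec(
                       "straight_tube", diameter_mm = 2, length_mm = 50,
                       z_angle_deg = 90, azimuth_deg = 0,
                       anchor_mm = c(18, 14, 5), contrast = 8)))
  sc <- generate_core(spec)
  oracle <- brute_cylinder_count(c(18, 14, 5), c(0, 0, 1), 50, 1,
                                 c(72L, 44L, 120L), sp)
  expect_identical(sc$truth$table$voxel_count, oracle)
  analytic <- pi * 1^2 * 50
  expect_lt(abs(sc$truth$table$volume_mm3 - analytic) / analytic, 0.10)
})

test_that("burrows leaving the core are clipped with a warning, empty ones error", {
  ctr <- small_centre()
  leaving <- burrow_spec("straight_tube", diameter_mm = 2, length_mm = 40,
                         z_angle_deg = 0, azimuth_deg = 0,
                         anchor_mm = c(ctr[1], ctr[2] - 5, 20), contrast = 8)
  expect_warning(sc <- generate_core(small_scene(list(leaving), seed = 2)),
                 "burrow 1 clipped")
  expect_true(sc$truth$table$clipped[1])
  outside <- burrow_spec("straight_tube", diameter_mm = 2, length_mm = 10,
                         z_angle_deg = 90, azimuth_deg = 0,
                         anchor_mm = c(1, 1, 10), contrast = 8)
  expect_error(suppressWarnings(generate_core(small_scene(list(outside)))),
               "burrow 1")
})

test_that("attenuation levels follow the scene statistics", {
  spec <- small_scene(list(small_tube(90, contrast = 8)), seed = 9, nz = 60L)
  sc <- generate_core(spec)
  air <- sc$volume$data[1, 1, 1]
  expect_equal(air, spec$host_mean - 10 * spec$host_sigma)
  fill_vals <- sc$volume$data[sc$truth$label_volume$labels == 1L]
  expect_equal(mean(fill_vals), spec$host_mean + 8 * spec$host_sigma,
               tolerance = 0.05)
})

test_that("preset scenes honour their advertised construction", {
  tv <- preset_scene("tiny_vertical", seed = 5)
  expect_true(all(vapply(tv$burrows, function(b) b$z_angle_deg, 1) >= 70))
  expect_true(all(vapply(tv$burrows, function(b) b$diameter_mm, 1) <= 1.0))
  th <- preset_scene("thick_horizontal", seed = 5)
  expect_true(all(vapply(th$burrows, function(b) b$diameter_mm, 1) > 5))
  expect_length(th$burrows, 8L)
  br <- preset_scene("branched", seed = 5)
  expect_true(all(vapply(br$burrows, function(b) b$kind, "") ==
                    "branched_network"))
  expect_error(preset_scene("nope"), "tiny_vertical")
  # determinism: same name and seed give the identical spec
  expect_identical(preset_scene("mixed", seed = 7), preset_scene("mixed", seed = 7))
})

test_that("the mixed preset alternates orientation-dominated depth bands", {
  spec <- preset_scene("mixed", seed = 2)
  bands <- attr(spec, "bands")
  expect_equal(bands$klass, c("V", "H", "V", "H"))
  # construction truth: per band, the dominant class holds > 50% of volume
  za <- vapply(spec$burrows, function(b) b$z_angle_deg, 1)
  zmid <- vapply(spec$burrows, function(b)
    b$anchor_mm[3] + b$length_mm / 2 *
      ichnoCT:::direction_from_angles(b$z_angle_deg, b$azimuth_deg)[3], 1)
  vol <- vapply(spec$burrows, function(b)
    pi * (b$diameter_mm / 2)^2 * b$length_mm, 1)
  for (i in seq_len(nrow(bands))) {
    in_band <- zmid / 10 >= bands$top_cm[i] & zmid / 10 < bands$base_cm[i]
    vert <- za[in_band] >= 45
    share <- sum(vol[in_band][vert]) / sum(vol[in_band])
    if (bands$klass[i] == "V") expect_gt(share, 0.5) else expect_lt(share, 0.5)
  }
})

test_that("branched networks produce pinch-and-swell single components", {
  b <- burrow_spec("branched_network", diameter_mm = 1.2, length_mm = 25,
                   z_angle_deg = 50, azimuth_deg = 30,
                   anchor_mm = c(small_centre()[1], small_centre()[2] - 7, 8),
                   contrast = 8, modulation_amplitude = 0.35, n_branches = 5L)
  sc <- suppressWarnings(generate_core(small_scene(list(b), seed = 13)))
  expect_gt(sc$truth$table$voxel_count, 100)
  expect_identical(max(sc$truth$label_volume$labels), 1L)
})
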