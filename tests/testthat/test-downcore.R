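# hand-built label volumes with known per-slice composition

profile_fixture <- function() {
  labs <- array(0L, dim = c(10L, 10L, 6L))
  labs[1:5, 1:2, 2] <- 1L          # 10 voxels of a vertical component
  labs[1:6, 1:5, 4] <- 1L          # 30 voxels vertical
  labs[7:8, 1:5, 4] <- 2L          # 10 voxels horizontal
  comp <- data.frame(id = 1:2,
                     orientation_class = c("sub_vertical", "sub_horizontal"))
  vol <- core_volume(array(0, dim = dim(labs)), c(1, 1, 1))
  list(lv = label_volume(labs, c(1, 1, 1)), comp = comp, vol = vol)
}

test_that("slice orientation percentages match brute-force voxel counts", {
  f <- profile_fixture()
  prof <- slice_profiles(f$lv, f$comp, f$vol)
  expect_equal(prof$pct_vertical[2], 100)
  expect_equal(prof$pct_horizontal[2], 0)
  expect_equal(prof$pct_vertical[4], 75)     # 30 of 40 voxels
  expect_equal(prof$fill_voxels[4], 40L)
  # empty slice
  expect_equal(prof$pct_vertical[1], 0)
  expect_equal(prof$bioturbated_pct[1], 0)
  # bioturbated fraction against a direct count
  expect_equal(prof$bioturbated_pct,
               100 * apply(f$lv$labels > 0, 3, sum) / (10 * 10))
  # a label without a component record is an error naming it
  bad <- f$comp[1, , drop = FALSE]
  expect_error(slice_profiles(f$lv, bad, f$vol), "2")
})

test_that("orientation percentages are conserved on random label fields", {
  ichnoCT:::with_seed(71, for (rep in 1:5) {
    labs <- array(sample(0:4, 8 * 8 * 10, replace = TRUE,
                         prob = c(0.8, rep(0.05, 4))), dim = c(8L, 8L, 10L))
    comp <- data.frame(id = 1:4, orientation_class = sample(
      c("sub_vertical", "sub_horizontal"), 4, replace = TRUE))
    vol <- core_volume(array(0, dim = dim(labs)), c(1, 1, 1))
    prof <- slice_profiles(label_volume(labs, c(1, 1, 1)), comp, vol)
    nonempty <- prof$fill_voxels > 0
    expect_true(all(abs(prof$pct_vertical[nonempty] +
                          prof$pct_horizontal[nonempty] - 100) < 1e-9))
    empty <- !nonempty
    expect_true(all(prof$pct_vertical[empty] == 0 &
                      prof$pct_horizontal[empty] == 0))
  })
})

fake_profiles <- function(pct_vertical, fill = 100L, dz_cm = 0.5) {
  n <- length(pct_vertical)
  vert <- as.integer(round(fill * pct_vertical / 100))
  data.frame(slice_index = seq_len(n), depth_cm = (seq_len(n) - 0.5) * dz_cm,
             pct_vertical = pct_vertical, pct_horizontal = 100 - pct_vertical,
             fill_voxels = fill, vertical_voxels = vert,
             horizontal_voxels = fill - vert, retained_voxels = 1000L,
             bioturbated_pct = 100 * fill / 1000)
}

test_that("interval classification handles uniform and mixed sections", {
  allv <- classify_intervals(fake_profiles(rep(100, 40)))
  expect_identical(nrow(allv), 1L)
  expect_identical(allv$klass, "V")
  expect_equal(allv$top_cm, 0)
  expect_equal(allv$base_cm, 20)
  even <- classify_intervals(fake_profiles(rep(50, 40)))
  expect_identical(even$klass, "V/H")
  expect_error(classify_intervals(fake_profiles(rep(50, 40)), window_cm = 0.1),
               "slice spacing")
})

test_that("interval labels tile the section and inherit over barren gaps", {
  pv <- c(rep(100, 20), rep(0, 20))
  prof <- fake_profiles(pv)
  prof$fill_voxels[18:22] <- 0L        # barren gap at the V/H transition
  prof$vertical_voxels[18:22] <- 0L
  prof$horizontal_voxels[18:22] <- 0L
  iv <- classify_intervals(prof, window_cm = 1)
  expect_equal(iv$top_cm[1], 0)
  expect_equal(iv$base_cm[nrow(iv)], 20)
  expect_true(all(abs(utils::head(iv$base_cm, -1) -
                        utils::tail(iv$top_cm, -1)) < 1e-9))
  expect_identical(iv$klass[1], "V")
  expect_identical(iv$klass[nrow(iv)], "H")
})

test_that("BI grades follow the band table and stay monotone", {
  expect_equal(bi_grade(0, bi_bands()), 0)
  expect_equal(bi_grade(100, bi_bands()), 6)
  expect_equal(bi_grade(50, bi_bands()), 3)
  pct <- seq(0, 100, by = 0.5)
  expect_true(all(diff(bi_grade(pct, bi_bands())) >= 0))
  bad <- bi_bands(); bad$max_pct[3] <- 1
  expect_error(bi_grade(50, bad), "monotone")
})

test_that("the BI log bins the profile and grades its means", {
  prof <- fake_profiles(rep(100, 40))            # bioturbated_pct = 10
  prof$fill_voxels[1:8] <- 0L                    # first 4 cm barren
  prof$bioturbated_pct[1:8] <- 0
  bi <- bioturbation_index(prof, bin_cm = 2)
  expect_identical(nrow(bi), 10L)
  expect_equal(bi$bi[1:2], c(0, 0))
  expect_true(all(bi$bi[3:10] == 2))             # 10% -> grade 2
  expect_error(bioturbation_index(prof, bands = within(bi_bands(),
                                                       max_pct[2] <- 0)),
               "monotone")
})

test_that("combining BI logs never falls below either input", {
  ct <- data.frame(top_cm = c(0, 10), base_cm = c(10, 20), bi = c(4, 0))
  im <- data.frame(top_cm = c(0, 10), base_cm = c(10, 20), bi = c(0, 0))
  comb <- combine_bi(ct, im)
  expect_equal(comb$bi, c(4, 0))
  # disjoint assemblages earn one extra grade, capped at 6
  im2 <- data.frame(top_cm = 0, base_cm = 20, bi = 4, disjoint_flag = TRUE)
  ct2 <- data.frame(top_cm = 0, base_cm = 20, bi = c(4))
  expect_equal(combine_bi(ct2, im2)$bi, 5)
  im3 <- im2; im3$bi <- 6
  expect_equal(combine_bi(ct2, im3)$bi, 6)
  # disjoint coverage errors
  far <- data.frame(top_cm = 50, base_cm = 60, bi = 2)
  expect_error(combine_bi(ct, far), "overlap")
})

test_that("combined BI dominates both inputs on random log pairs", {
  ichnoCT:::with_seed(72, for (rep in 1:20) {
    n <- sample(3:8, 1)
    edges <- sort(stats::runif(n + 1, 0, 100))
    ct <- data.frame(top_cm = utils::head(edges, -1),
                     base_cm = utils::tail(edges, -1),
                     bi = sample(0:6, n, replace = TRUE))
    im <- data.frame(top_cm = utils::head(edges, -1),
                     base_cm = utils::tail(edges, -1),
                     bi = sample(0:6, n, replace = TRUE),
                     disjoint_flag = sample(c(TRUE, FALSE), n, replace = TRUE))
    comb <- combine_bi(ct, im)
    expect_true(all(comb$bi >= pmax(comb$bi_ct, comb$bi_image2d)))
    expect_true(all(comb$bi <= 6))
  })
})
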