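make_int_volume <- function(dims = c(12L, 10L, 5L), seed = 1) {
  ichnoCT:::with_seed(seed, core_volume(
    array(sample(0:4000, prod(dims), replace = TRUE), dim = dims),
    spacing_mm = c(0.351, 0.351, 0.5)))
}

test_that("TIFF stacks round-trip bit-faithfully and carry explicit spacing", {
  vol <- make_int_volume()
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(vol, path)
  back <- read_image_stack(path, spacing_mm = vol$spacing_mm)
  expect_identical(back$data, vol$data)
  expect_equal(back$spacing_mm, vol$spacing_mm)
  expect_error(read_image_stack(path), "spacing")
})

test_that("a stack of zero pages reads to a volume of zeros", {
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(array(0L, dim = c(8L, 6L, 5L)), path)
  vol <- read_image_stack(path, spacing_mm = c(1, 1, 1))
  expect_identical(dim(vol$data), c(8L, 6L, 5L))
  expect_true(all(vol$data == 0))
})

test_that("multi-channel and ragged pages are rejected", {
  rgb_path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, dim = c(6, 8, 3)), rgb_path)
  expect_error(read_image_stack(rgb_path, spacing_mm = c(1, 1, 1)),
               "single-channel")
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.2, 6, 8), p1)
  tiff::writeTIFF(matrix(0.2, 7, 8), p2)
  expect_error(read_image_stack(c(p1, p2), spacing_mm = c(1, 1, 1)), "ragged")
})

test_that("DICOM series round-trip to equal data and spacing", {
  vol <- make_int_volume(c(10L, 8L, 10L), seed = 3)
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- read_dicom_series(dir)
  expect_equal(back$data, vol$data)
  expect_equal(back$spacing_mm, vol$spacing_mm, tolerance = 1e-6)
})

test_that("shuffled slice filenames read identically to sorted ones", {
  vol <- make_int_volume(c(6L, 5L, 8L), seed = 4)
  dir1 <- withr::local_tempdir()
  write_dicom_series(vol, dir1)
  ref <- read_dicom_series(dir1)
  dir2 <- withr::local_tempdir()
  files <- list.files(dir1, full.names = TRUE)
  # adversarial names: lexicographic order is the reverse of depth order
  for (i in seq_along(files))
    file.copy(files[i], file.path(dir2, sprintf("s_%04d.dcm",
                                                length(files) - i + 1)))
  shuffled <- read_dicom_series(dir2)
  expect_identical(shuffled$data, ref$data)
  expect_equal(shuffled$spacing_mm, ref$spacing_mm)
})

test_that("a directory mixing two series is rejected", {
  v1 <- make_int_volume(c(6L, 5L, 3L), seed = 5)
  dir <- withr::local_tempdir()
  write_dicom_series(v1, dir)
  other <- withr::local_tempdir()
  write_dicom_series(v1, other, series_uid = "2.25.909090.7")
  file.copy(list.files(other, full.names = TRUE)[1],
            file.path(dir, "intruder.dcm"))
  expect_error(read_dicom_series(dir), "series UID")
})

test_that("our DICOM files agree with an independent reader", {
  vol <- make_int_volume(c(7L, 6L, 4L), seed = 6)
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, glob, pydicom",
    "files = sorted(glob.glob(sys.argv[1] + '/*.dcm'))",
    "tot = rows = cols = 0",
    "for f in files:",
    "    d = pydicom.dcmread(f)",
    "    a = d.pixel_array",
    "    rows, cols = a.shape",
    "    tot += int(a.astype('int64').sum())",
    "print(len(files), rows, cols, tot)"), script)
  out <- suppressWarnings(system2("python", c(script, dir), stdout = TRUE))
  parts <- as.numeric(strsplit(utils::tail(out, 1), " ")[[1]])
  expect_equal(parts, c(4, 6, 7, sum(vol$data)))
})

test_that("burrow and profile tables round-trip through CSV", {
  empty <- parameterise_components(
    label_volume(array(0L, dim = c(4L, 4L, 4L)), c(1, 1, 1)))
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- write_tables(empty, data.frame(), prefix)
  expect_identical(nrow(utils::read.csv(paths[1])), 0L)

  labs <- array(0L, dim = c(6L, 6L, 8L))
  labs[3, 3, 2:7] <- 1L
  lv <- label_volume(labs, c(0.5, 0.5, 0.5))
  comp <- parameterise_components(lv)
  vol <- core_volume(array(1000, dim = dim(labs)), c(0.5, 0.5, 0.5))
  prof <- slice_profiles(lv, comp, vol)
  paths <- write_tables(comp, prof, prefix)
  b <- utils::read.csv(paths[1])
  expect_identical(nrow(b), 1L)
  expect_true(all(c("id", "volume_mm3", "z_angle_deg", "size_class") %in%
                    names(b)))
  p <- utils::read.csv(paths[2])
  expect_equal(signif(p$bioturbated_pct, 6), signif(prof$bioturbated_pct, 6))
  expect_equal(signif(p$pct_vertical, 6), signif(prof$pct_vertical, 6))
})

test_that("scene specs serialise to YAML and back", {
  spec <- small_scene(list(small_tube(33, azimuth_deg = 120, length_mm = 12)),
                      seed = 8, nz = 40L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_spec(spec, path)
  back <- read_scene_spec(path)
  expect_equal(back, spec, tolerance = 1e-12)
  # identical generation from the round-tripped spec
  expect_identical(generate_core(back)$volume$data,
                   generate_core(spec)$volume$data)
})

test_that("the 2D-image ichnology table reader validates its input", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(top_cm = c(0, 10), base_cm = c(10, 20),
                              bi = c(2, 4), taxa = c("Chondrites", ""),
                              disjoint_flag = c(TRUE, FALSE)),
                   path, row.names = FALSE)
  tab <- read_image2d_table(path)
  expect_identical(tab$disjoint_flag, c(TRUE, FALSE))
  utils::write.csv(data.frame(top_cm = 0, base_cm = 10, bi = 9), path,
                   row.names = FALSE)
  expect_error(read_image2d_table(path), "0..6")
})
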