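test_that("volume construction validates spacing and shape", {
  expect_error(new_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  expect_error(new_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  v <- new_volume(array(1:8, c(2, 2, 2)), c(0.5, 0.25, 0.25))
  expect_s3_class(v, "volume")
  expect_identical(v$spacing, c(0.5, 0.25, 0.25))
})

test_that("index-physical round trip is the identity for in-bounds voxels", {
  v <- new_volume(array(0, c(3, 4, 5)), c(0.5, 0.25, 0.125), origin = c(-3, 2, 7))
  idx <- as.matrix(expand.grid(1:3, 1:4, 1:5))
  back <- world_to_voxel(v, voxel_to_world(v, idx))
  expect_equal(back, unname(idx), tolerance = 1e-12, ignore_attr = TRUE)
  # declared convention: index (1,1,1) sits at the origin, steps are spacing
  expect_equal(as.numeric(voxel_to_world(v, c(1, 1, 1))), c(-3, 2, 7))
  expect_equal(as.numeric(voxel_to_world(v, c(2, 1, 1))), c(-3, 2, 7.5))
  expect_equal(as.numeric(voxel_to_world(v, c(1, 2, 1))), c(-3, 2.25, 7))
  expect_equal(as.numeric(voxel_to_world(v, c(1, 1, 2))), c(-2.875, 2, 7))
})

test_that("PNG stack reading honours sort order, sidecar and overrides", {
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    png::writePNG(matrix(i / 10, 4, 4), file.path(dir, sprintf("s%02d.png", i)))
  }
  expect_error(read_volume(dir), "spacing")
  jsonlite::write_json(list(dz = 0.5, dy = 0.25, dx = 0.25),
                       file.path(dir, "spacing.json"), auto_unbox = TRUE)
  v <- read_volume(dir)
  expect_equal(dim(v$data), c(3L, 4L, 4L))
  expect_equal(v$spacing, c(0.5, 0.25, 0.25))
  expect_equal(v$data[2, 1, 1], 0.2, tolerance = 1e-3)  # ascending filename order
  v2 <- read_volume(dir, spacing_override = c(1, 1, 1))
  expect_equal(v2$spacing, c(1, 1, 1))
})

test_that("PNG stacks with inconsistent slice sizes are rejected", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 4, 5), file.path(dir, "b.png"))
  jsonlite::write_json(list(dz = 1, dy = 1, dx = 1),
                       file.path(dir, "spacing.json"), auto_unbox = TRUE)
  expect_error(read_volume(dir), "inconsistent slice dimensions")
})

test_that("NIfTI round trip preserves integer grids exactly and floats to 1e-6", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  vi <- new_volume(array(sample.int(1000, 60), c(3, 4, 5)), c(0.5, 0.25, 0.25),
                   origin = c(1, 2, 3))
  write_volume(vi, f)
  back <- read_volume(f)
  expect_equal(back$data, vi$data, ignore_attr = TRUE)
  expect_equal(back$spacing, vi$spacing)
  expect_equal(back$origin, vi$origin)

  set.seed(7)
  vf <- new_volume(array(rnorm(60), c(3, 4, 5)), c(1, 1, 1))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vf, f2)
  expect_equal(read_volume(f2)$data, vf$data, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("label volumes round trip with their name table", {
  lab <- array(0L, c(3, 4, 4)); lab[2, 2:3, 2:3] <- 1L; lab[3, 1, 1] <- 5L
  tab <- data.frame(id = c(1L, 5L), name = c("pituitary", "optic_nerve"))
  lv <- new_label_volume(lab, tab, c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".nii")
  write_label_volume(lv, f)
  back <- read_label_volume(f, sub("\\.nii$", "_labels.csv", f))
  expect_identical(back$labels, lv$labels)
  expect_equal(back$table, lv$table, ignore_attr = TRUE)
  # grid labels missing from the table are a contract violation
  expect_error(new_label_volume(lab, tab[1, ], c(1, 1, 1)), "absent from table")
})

test_that("isotropic resampling preserves constants, extent and linearity", {
  v <- new_volume(array(7, c(5, 8, 8)), c(0.5, 0.25, 0.25))
  expect_identical(resample_isotropic(v, 0.25)$spacing, rep(0.25, 3))
  r <- resample_isotropic(v, 0.5)
  expect_true(all(r$data == 7))
  # physical extent preserved within one voxel on every axis
  ext_in <- (dim(v$data) - 1) * v$spacing
  ext_out <- (dim(r$data) - 1) * r$spacing
  expect_true(all(abs(ext_in - ext_out) <= 0.5 + 1e-9))
  # identity when already at target spacing
  vi <- new_volume(array(rnorm(27), c(3, 3, 3)), c(1, 1, 1))
  expect_identical(resample_isotropic(vi, 1)$data, vi$data)
  expect_error(resample_isotropic(vi, -1), "positive")
})

test_that("upsampled mid-slice is the closed-form linear interpolant", {
  a <- array(0, c(2, 3, 3)); a[1, , ] <- 2; a[2, , ] <- 6
  v <- new_volume(a, c(0.5, 0.25, 0.25))
  r <- resample_isotropic(v, 0.25)
  expect_equal(dim(r$data)[1], 3L)       # closed-extent convention
  expect_true(all(r$data[2, , ] == 4))   # mean of the two neighbours
  expect_true(all(r$data[1, , ] == 2) && all(r$data[3, , ] == 6))
})

test_that("resampling back to the original spacing reproduces a constant volume", {
  v <- new_volume(array(3.5, c(4, 6, 6)), c(0.5, 0.25, 0.25))
  there <- resample_isotropic(v, 0.5)
  back <- resample_isotropic(there, 0.25)
  expect_true(all(back$data == 3.5))
})
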