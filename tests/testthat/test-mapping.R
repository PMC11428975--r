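make_labels <- function() {
  lab <- array(0L, c(6, 10, 10))
  lab[2:4, 3:6, 3:6] <- 1L
  lab[5, 8, 8] <- 2L
  new_label_volume(lab, data.frame(id = 1:2, name = c("pituitary", "marker")),
                   c(1, 1, 1))
}

test_that("identity mapping reproduces the atlas label support bitwise", {
  lv <- make_labels()
  subject <- new_volume(array(0, dim(lv$labels)), lv$spacing, lv$origin)
  m <- map_roi(lv, "pituitary", transform_identity(), subject)
  expect_identical(m$mask, array(lv$labels == 1L, dim(lv$labels)))
  m2 <- map_roi(lv, c(1L, 2L), transform_identity(), subject)
  expect_identical(m2$mask, array(lv$labels > 0L, dim(lv$labels)))
})

test_that("whole-voxel translations shift the mapped support exactly", {
  lv <- make_labels()
  subject <- new_volume(array(0, dim(lv$labels)), lv$spacing, lv$origin)
  tr <- rigid_transform(diag(3), c(2, 1, 1))           # (x, y, z) mm = voxels
  m <- map_roi(lv, 1L, tr, subject)
  shifted <- array(FALSE, dim(lv$labels))
  shifted[3:5, 4:7, 5:8] <- TRUE                       # +1 slice, +1 row, +2 col
  expect_identical(m$mask, shifted)
})

test_that("transforms that push the ROI off-grid warn and return empty", {
  lv <- make_labels()
  subject <- new_volume(array(0, dim(lv$labels)), lv$spacing, lv$origin)
  tr <- rigid_transform(diag(3), c(500, 0, 0))
  expect_warning(m <- map_roi(lv, 1L, tr, subject), "empty")
  expect_false(any(m$mask))
})

test_that("unknown ROI names and ids are rejected with the available set", {
  lv <- make_labels()
  subject <- new_volume(array(0, dim(lv$labels)), lv$spacing, lv$origin)
  expect_error(map_roi(lv, "optic nerve", transform_identity(), subject),
               "available: pituitary, marker")
  expect_error(map_roi(lv, 7L, transform_identity(), subject), "available")
})

test_that("per-slice recall is intersection over reference, per axial slice", {
  ref <- array(FALSE, c(4, 12, 12)); ref[2, 2:6, 3:4] <- TRUE   # 10 voxels
  mapped <- array(FALSE, c(4, 12, 12))
  mapped[2, 2:5, 3:4] <- TRUE                          # 8 of the 10
  mapped[2, 8:12, 8:12] <- TRUE                        # 25 spurious voxels
  rs <- recall_per_slice(mapped, ref)
  expect_equal(rs$slice, 2L)
  expect_equal(rs$recall, 8 / 10)                      # numerator: intersection
  expect_equal(recall_per_slice(ref, ref)$recall, 1)
  none <- array(FALSE, dim(ref))
  expect_equal(recall_per_slice(none, ref)$recall, 0)
  expect_error(recall_per_slice(mapped, none), "positive reference")
  expect_error(recall_per_slice(mapped, ref[1:3, , ]), "congruent")
})

test_that("recall never decreases when the mapped region grows", {
  set.seed(17)
  ref <- array(runif(4 * 8 * 8) < 0.3, c(4, 8, 8))
  mapped <- array(runif(4 * 8 * 8) < 0.3, c(4, 8, 8))
  r1 <- recall_per_slice(mapped, ref)$recall
  grown <- mapped | array(runif(4 * 8 * 8) < 0.3, c(4, 8, 8))
  r2 <- recall_per_slice(grown, ref)$recall
  expect_true(all(r2 >= r1))
})

test_that("slice_range restricts the evaluated slices", {
  ref <- array(TRUE, c(5, 4, 4))
  mapped <- ref
  rs <- recall_per_slice(mapped, ref, slice_range = c(2, 3))
  expect_equal(rs$slice, 2:3)
})

test_that("recall summary matches independent sums, order statistics and CI", {
  x <- c(0.91, 0.72, 0.88, 0.99, 0.64)
  s <- summarize_recall(x)
  expect_equal(s$max, 0.99)
  expect_equal(s$min, 0.64)
  expect_equal(s$median, sort(x)[3])
  expect_equal(s$mean, sum(x) / length(x), tolerance = 1e-12)
  sd_manual <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(s$ci95, mean(x) + c(-1, 1) * 1.96 * sd_manual / sqrt(5),
               tolerance = 1e-12)
  # even n: median is the mean of the middle order statistics
  s4 <- summarize_recall(c(0.2, 0.4, 0.6, 1.0))
  expect_equal(s4$median, 0.5)
  # single value: all statistics collapse, no CI
  s1 <- summarize_recall(0.8838)
  expect_equal(c(s1$max, s1$min, s1$median, s1$mean), rep(0.8838, 4))
  expect_null(s1$ci95)
  expect_error(summarize_recall(numeric(0)), "empty")
  expect_error(summarize_recall(c(0.5, 1.2)), "0, 1")
})

test_that("mapping through the ground-truth transform recovers subject ROIs", {
  ph <- test_atlas()
  sub <- derive_subject(ph$volume, ph$labels, scale = 0.93,
                        rotation = c(10, 0, 0), translation = c(20, 5, 0))
  for (roi in c("pituitary", "optic_nerve")) {
    m <- map_roi(ph$labels, roi, sub$truth$transform, sub$volume)
    ref <- roi_mask_from_labels(sub$labels, roi)
    s <- summarize_recall(recall_per_slice(m, ref))
    expect_gte(s$mean, 0.9)                            # resampling-only loss
  }
})
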