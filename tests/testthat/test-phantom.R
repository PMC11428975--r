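test_that("the noise-free phantom binarizes back to the analytic solid", {
  spec <- phantom_spec(shape = c(48, 72, 64), head_semiaxes = c(20, 25, 21),
                       nose_length = 12, nose_radius = 5, eye_offset = 8,
                       eye_radius = 4)
  ph <- generate_atlas(spec, rois = list(
    list(id = 1L, name = "pituitary", shape = "sphere",
         center = c(31.5, 35.5, 23.5), radius = 3)))
  g <- tspr:::world_grids(spec$shape, spec$spacing)
  solid <- tspr:::head_membership(spec, g$x, g$y, g$z)
  expect_identical(as.vector(ph$volume$data > 50), solid)
  expect_true(all(ph$volume$data %in% c(0, 100)))
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- phantom_spec(shape = c(32, 48, 40), head_semiaxes = c(14, 16, 12),
                       nose_length = 8, nose_radius = 4, eye_offset = 6,
                       eye_radius = 3, noise_sigma = 4, seed = 99)
  a <- generate_atlas(spec, rois = list())
  b <- generate_atlas(spec, rois = list())
  expect_identical(a$volume$data, b$volume$data)
  spec2 <- phantom_spec(shape = c(32, 48, 40), head_semiaxes = c(14, 16, 12),
                        nose_length = 8, nose_radius = 4, eye_offset = 6,
                        eye_radius = 3, noise_sigma = 4, seed = 100)
  expect_false(identical(a$volume$data, generate_atlas(spec2, rois = list())$volume$data))
})

test_that("the nose tip is the foreground voxel with the largest anterior coordinate", {
  ph <- test_atlas()
  fg <- which(ph$volume$data > 50, arr.ind = TRUE)
  tip <- fg[which.max(fg[, 2]), ]
  w <- voxel_to_world(ph$volume, tip)
  ctr_x <- (dim(ph$volume$data)[3] - 1) / 2
  ctr_z <- (dim(ph$volume$data)[1] - 1) / 2
  expect_lt(abs(w[1] - ctr_x), 2)                    # midline in x
  expect_lt(abs(w[3] - (ctr_z + 0.05 * 42)), 2)      # nose height
})

test_that("rois outside the head are refused", {
  spec <- phantom_spec(shape = c(32, 48, 40), head_semiaxes = c(12, 14, 12),
                       nose_length = 8, nose_radius = 4, eye_offset = 5,
                       eye_radius = 3)
  expect_error(generate_atlas(spec, rois = list(
    list(id = 1L, name = "stray", shape = "sphere",
         center = c(0, 0, 0), radius = 3))), "outside the head")
})

test_that("identity-parameter subjects reproduce the atlas on its own grid", {
  ph <- test_atlas()
  sub <- derive_subject(ph$volume, ph$labels, out_shape = dim(ph$volume$data))
  expect_equal(unclass(sub$truth$transform), diag(4))
  expect_equal(sub$volume$data, ph$volume$data, tolerance = 1e-12)
  expect_identical(sub$labels$labels, ph$labels$labels)
})

test_that("ground-truth transform maps atlas ROI centroids onto subject ROI centroids", {
  ph <- test_atlas()
  sub <- derive_subject(ph$volume, ph$labels, scale = 0.93,
                        rotation = c(10, 0, 0), translation = c(20, 5, 0))
  for (id in ph$labels$table$id) {
    ai <- which(ph$labels$labels == id, arr.ind = TRUE)
    si <- which(sub$labels$labels == id, arr.ind = TRUE)
    ca <- colMeans(voxel_to_world(ph$labels, ai))
    cs <- colMeans(voxel_to_world(sub$labels, si))
    mapped <- as.numeric(apply_transform(sub$truth$transform, ca))
    expect_lt(sqrt(sum((mapped - cs)^2)), 1)          # within one voxel
  }
})

test_that("subjects are framed inside their grid; fully-lost heads error", {
  ph <- test_atlas()
  sub <- derive_subject(ph$volume, ph$labels, scale = 0.9,
                        rotation = c(0, 0, 20), translation = c(-25, 30, 10))
  fg <- which(sub$volume$data > 50, arr.ind = TRUE)
  expect_gt(nrow(fg), 1000)
  expect_true(all(fg[, 1] > 1 & fg[, 1] < dim(sub$volume$data)[1]))
  expect_true(all(fg[, 2] > 1 & fg[, 2] < dim(sub$volume$data)[2]))
  expect_true(all(fg[, 3] > 1 & fg[, 3] < dim(sub$volume$data)[3]))
  expect_error(derive_subject(ph$volume, ph$labels, translation = c(0, 500, 0),
                              out_shape = dim(ph$volume$data)),
               "outside the subject grid")
})

test_that("a missing-region defect changes the surface only inside its sphere", {
  ph <- test_atlas()
  clean <- derive_subject(ph$volume, ph$labels, scale = 0.95,
                          rotation = c(5, 0, 0), translation = c(5, 0, 0))
  fg <- which(clean$volume$data > 50, arr.ind = TRUE)
  tip <- voxel_to_world(clean$volume, fg[which.max(fg[, 2]), ])
  defect <- list(type = "missing_region",
                 center = as.numeric(tip) - c(0, 2, 10), radius = 7)
  broken <- derive_subject(ph$volume, ph$labels, scale = 0.95,
                           rotation = c(5, 0, 0), translation = c(5, 0, 0),
                           defects = list(defect))
  sc <- surface_from_volume(clean$volume, contour_params(threshold = 50))
  sb <- surface_from_volume(broken$volume, contour_params(threshold = 50))
  dc <- sqrt(colSums((t(sc[, 1:3]) - defect$center)^2))
  db <- sqrt(colSums((t(sb[, 1:3]) - defect$center)^2))
  margin <- defect$radius + 2
  away_c <- sc[dc > margin, ]; away_b <- sb[db > margin, ]
  # identical point sets away from the defect
  expect_equal(nrow(away_c), nrow(away_b))
  expect_equal(sort(away_c[, 1] * 1e6 + away_c[, 2] * 1e3 + away_c[, 3]),
               sort(away_b[, 1] * 1e6 + away_b[, 2] * 1e3 + away_b[, 3]),
               tolerance = 1e-9)
})
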