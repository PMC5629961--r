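test_that("label transformation maps background/gland to the malignancy-specific classes", {
  lab <- matrix(0L, 6, 6)
  lab[2:3, 2:3] <- 1L
  lab[5, 5:6] <- 2L

  ben <- transform_labels(lab, malignant = FALSE)
  expect_setequal(unique(as.vector(ben)), c(0L, 1L))
  expect_equal(sum(ben == 1L), sum(lab > 0L))

  mal <- transform_labels(lab, malignant = TRUE)
  expect_setequal(unique(as.vector(mal)), c(2L, 3L))
  expect_equal(sum(mal == 3L), sum(lab > 0L))

  # invertibility to the binary gland mask
  set.seed(2)
  for (rep in 1:5) {
    r <- matrix(sample(0:3, 64, TRUE), 8, 8)
    for (flag in c(TRUE, FALSE)) {
      four <- transform_labels(r, flag)
      expect_identical(four %in% c(1L, 3L), as.vector(r > 0L))
    }
  }
  expect_error(transform_labels(lab, NULL), "flag")
})

test_that("separator polylines rasterize to binary masks of the right extent", {
  expect_equal(rasterize_separators(list(), c(10, 12)), matrix(0L, 10, 12))

  # horizontal 10-pixel segment at thickness 1 covers exactly 10 pixels
  seg <- rasterize_separators(list(cbind(c(2, 11), c(5, 5))), c(10, 12),
                              thickness = 1)
  expect_equal(sum(seg), 10)
  expect_true(all(seg[5, 2:11] == 1L))
  expect_true(all(seg %in% c(0L, 1L)))
  expect_identical(dim(seg), c(10L, 12L))

  # out-of-bounds points are clipped with a warning
  expect_warning(
    out <- rasterize_separators(list(cbind(c(-3, 5), c(2, 2))), c(8, 8),
                                thickness = 1),
    "clipped")
  expect_true(all(out %in% c(0L, 1L)))

  thick <- rasterize_separators(list(cbind(c(3, 8), c(4, 4))), c(10, 10),
                                thickness = 3)
  expect_gt(sum(thick), sum(seg))
})

test_that("balanced sampling is exact, seeded, and center-label consistent", {
  set.seed(10)
  ch <- matrix(runif(60 * 60, 0, 255), 60, 60)
  lab <- matrix(0L, 60, 60)
  lab[20:40, 20:40] <- 1L
  lab[5:10, 45:55] <- 2L

  ds <- sample_balanced_patches(ch, lab, per_class = 25, patch_size = 11,
                                seed = 42)
  expect_equal(as.vector(table(ds$labels)), rep(25, 3))
  expect_equal(length(ds$labels), 75)
  # stored label equals the label raster at each center
  expect_equal(ds$labels, lab[ds$centers])
  # patch center pixel equals the channel at the center
  mid <- (11 + 1) / 2
  expect_equal(ds$patches[mid, mid, ], ch[ds$centers])
  # no duplicate centers within a class when enough pixels exist
  expect_false(any(duplicated(cbind(ds$centers, ds$labels))))

  ds2 <- sample_balanced_patches(ch, lab, per_class = 25, patch_size = 11,
                                 seed = 42)
  expect_identical(ds$centers, ds2$centers)

  expect_error(
    sample_balanced_patches(ch, lab, per_class = 5, classes = c(0, 9),
                            patch_size = 11),
    "class 9")
  expect_warning(
    sample_balanced_patches(ch, lab, per_class = 5000, patch_size = 11,
                            seed = 1, classes = 2),
    "replacement")
})

test_that("rotation augmentation returns the requested rotated copies", {
  set.seed(3)
  patch <- matrix(runif(441, 0, 255), 21, 21)
  rots <- augment_rotations(patch)
  expect_length(rots, 9)
  expect_equal(attr(rots, "angles"), 36 * 1:9)

  # a full turn is the identity up to interpolation error
  full <- glandseg:::.rotate_patch(patch, 360)
  expect_equal(full, patch, tolerance = 1e-8)

  # the center pixel is preserved by rotation about the center
  for (r in rots) expect_equal(r[11, 11], patch[11, 11], tolerance = 1e-8)

  expect_error(augment_rotations(matrix(0, 3, 4)), "square")
})
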