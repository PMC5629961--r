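test_that("colour deconvolution inverts the optical-density mixing model", {
  m <- he2_stain_matrix()
  expect_equal(unname(sqrt(rowSums(m^2))), rep(1, 3), tolerance = 1e-12)

  # pure white carries zero optical density, hence zero stain everywhere
  white <- array(255, dim = c(1, 1, 3))
  expect_equal(as.vector(color_deconvolve(white)$channels), c(0, 0, 0),
               tolerance = 1e-12)

  # a pixel with the transmitted colour of stain 1 at unit density
  I1 <- array(255 * 10^(-m[1, ]), dim = c(1, 1, 3))
  expect_equal(as.vector(color_deconvolve(I1)$channels), c(1, 0, 0),
               tolerance = 1e-9)

  # round trip on random RGB fixtures is an identity within 1 intensity level
  set.seed(4)
  for (rep in 1:5) {
    img <- array(runif(24 * 18 * 3, 0, 255), dim = c(24, 18, 3))
    rec <- reconstruct_rgb(color_deconvolve(img))
    expect_lt(max(abs(rec - img)), 1)
  }

  expect_error(color_deconvolve(matrix(0, 5, 5)), "RGB")
  expect_error(color_deconvolve(white, matrix(1, 3, 3)), "singular")
})

test_that("CLAHE preserves range, widens low-contrast inputs, fixes constants", {
  const <- matrix(100, 32, 32)
  out <- apply_clahe(const, 2, c(4, 4))
  expect_equal(stats::sd(out), 0)           # constant stays constant
  out2 <- apply_clahe(out, 2, c(4, 4))      # idempotent on equalized constant
  expect_equal(out2, out, tolerance = 2)

  ramp <- matrix(rep(seq(100, 140, length.out = 40), each = 40), 40, 40)
  eq <- apply_clahe(ramp, 2, c(4, 4))
  expect_gt(diff(range(eq)), diff(range(ramp)))  # contrast strictly widened
  expect_gte(min(eq), 0)
  expect_lte(max(eq), 255)

  expect_error(apply_clahe(matrix(0, 4, 4), 2, c(8, 8)), "larger")
})

test_that("resampling follows the floor-dimension and mode contracts", {
  img <- matrix(runif(775 * 522), 775, 522)
  half <- resample(img, 0.5, mode = "area")
  expect_identical(dim(half), c(387L, 261L))

  # down-by-0.5 then up-to-original restores the original dimensions
  back <- resample(half, dims = dim(img), mode = "bilinear")
  expect_identical(dim(back), dim(img))

  # constants are invariant under any interpolation
  const <- matrix(7, 20, 30)
  expect_equal(resample(const, 0.5, mode = "bilinear"), matrix(7, 10, 15))
  expect_equal(resample(const, 0.5, mode = "area"), matrix(7, 10, 15))

  # nearest mode never invents label values
  set.seed(1)
  lab <- matrix(sample(c(0L, 3L, 7L), 400, TRUE), 20, 20)
  down <- resample(lab, 0.37, mode = "nearest")
  expect_true(all(down %in% lab))
  up <- resample(lab, 2.3, mode = "nearest")
  expect_true(all(up %in% lab))

  expect_error(resample(img, -1), "positive")
  expect_error(resample(img, 0), "positive")
})

test_that("preprocess_image yields full and half resolution structure channels", {
  scene <- generate_scene(scene_config(size = c(64L, 80L), n_glands = 1L,
                                       seed = 3))
  pre <- preprocess_image(scene$image)
  expect_identical(dim(pre$full), c(64L, 80L))
  expect_identical(dim(pre$half), c(32L, 40L))
  expect_equal(attr(pre$half, "scale"), 0.5)
  expect_true(all(pre$full >= 0 & pre$full <= 255))
})
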