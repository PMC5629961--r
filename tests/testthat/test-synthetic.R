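test_that("scene generation honours its configuration and seed", {
  cfg <- scene_config(n_glands = 5L, seed = 11)
  sc <- generate_scene(cfg)
  expect_s3_class(sc, "synthetic_scene")
  expect_setequal(unique(sc$labels[sc$labels > 0]), 1:5)
  expect_identical(dim(sc$image), c(200L, 200L, 3L))
  expect_true(all(sc$image >= 0 & sc$image <= 255))

  # bit-identical under the same seed
  expect_identical(generate_scene(cfg), sc)

  # well-separated default scenes carry no separator annotation
  expect_equal(sum(sc$separator), 0)

  # malignant scenes exist and are flagged
  scm <- generate_scene(scene_config(malignant = TRUE, seed = 2))
  expect_true(scm$malignant)

  expect_error(generate_scene(scene_config(n_glands = 60L, seed = 1)),
               "packing")
})

test_that("touching scenes place separator annotations between paired glands", {
  sc <- generate_scene(scene_config(n_glands = 4L, touching_fraction = 1,
                                    touch_gap = 3, seed = 5))
  expect_gt(sum(sc$separator), 0)
  # separators live in the stroma, not inside glands
  expect_true(all(sc$labels[sc$separator > 0] == 0L))
  # each separator pixel is close to at least two distinct glands
  sep_px <- which(sc$separator > 0, arr.ind = TRUE)
  dmaps <- lapply(sort(unique(sc$labels[sc$labels > 0])), function(k)
    glandseg:::.distance_to(sc$labels == k))
  near_counts <- vapply(seq_len(nrow(sep_px)), function(i) {
    d <- vapply(dmaps, function(dm) dm[sep_px[i, 1], sep_px[i, 2]], numeric(1))
    sum(d <= sc$config$sep_gap_threshold + sc$config$sep_thickness)
  }, numeric(1))
  expect_true(all(near_counts >= 2))
})

test_that("probability fixtures reproduce the labels and stay normalised", {
  sc <- generate_scene(scene_config(n_glands = 3L, seed = 7))
  four <- transform_labels(sc$labels, sc$malignant)

  # noise-free, blur-free: per-pixel argmax recovers the four-class labels
  fx <- generate_probability_fixtures(sc$labels, sc$malignant)
  am <- apply(fx$maps, c(1, 2), which.max) - 1L
  expect_identical(am, matrix(as.integer(four), nrow(four), ncol(four)))

  # corrupted maps still sum to one per pixel
  fx2 <- generate_probability_fixtures(sc$labels, sc$malignant,
                                       flip_noise = 0.2, blur = 1.5,
                                       separator = sc$separator, seed = 3)
  tot <- fx2$maps[, , 1] + fx2$maps[, , 2] + fx2$maps[, , 3] + fx2$maps[, , 4]
  expect_lt(max(abs(tot - 1)), 1e-9)

  # reproducible under seed
  fx3 <- generate_probability_fixtures(sc$labels, sc$malignant,
                                       flip_noise = 0.2, blur = 1.5,
                                       separator = sc$separator, seed = 3)
  expect_identical(fx2, fx3)
})
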