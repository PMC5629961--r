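test_that("canonical architectures match the published layout", {
  obj <- build_network("object")
  sep <- build_network("separator")

  expect_equal(obj$n_classes, 4L)
  expect_equal(sep$n_classes, 2L)
  expect_equal(obj$K, 7L)

  kinds <- vapply(obj$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "conv"), 4L)
  expect_equal(sum(kinds == "fc"), 3L)
  expect_equal(kinds[1:6], rep(c("conv", "pool"), 3))  # pools follow conv 1-3 only

  # valid-convolution + floor-pooling size chain on the 101x101 input
  expect_equal(unname(spec_feature_sizes(obj)), c(91L, 45L, 39L, 19L, 15L, 7L, 5L))
  expect_equal(unname(spec_feature_sizes(sep)), c(93L, 46L, 40L, 20L, 16L, 8L, 6L))

  # architectural determinism: parameter count identical across builds
  expect_identical(n_parameters(build_network("object")), n_parameters(obj))
  expect_error(build_network("edge"), "arg")
  expect_error(network_spec("object", input_size = 15L), "collapses")
})

test_that("training separates a two-class intensity problem and is seeded", {
  tr <- make_intensity_patches(50, 2L, seed = 1)
  va <- make_intensity_patches(25, 2L, seed = 2)
  cfg <- train_config(batch_size = 20L, max_epochs = 30L, patience = 6L,
                      seed = 7)
  net <- train_network(small_spec("separator"), tr, va, cfg)

  expect_true(net$trained)
  expect_lt(min(net$history$valid_error), 0.05)
  expect_true(all(c("epoch", "train_error", "valid_error") %in%
                    names(net$history)))
  # stopping: no more than patience epochs beyond the best one
  expect_lte(nrow(net$history), net$best_epoch + cfg$patience)

  # identical seed and data reproduce the first-epoch errors exactly
  net2 <- train_network(small_spec("separator"), tr, va, cfg)
  expect_identical(net$history$train_error[1], net2$history$train_error[1])

  # class-count mismatch is rejected up front
  expect_error(train_network(small_spec("object"), tr, va, cfg), "output units")
})

test_that("the optimisation schedules follow the configured ramps", {
  cfg <- train_config()
  expect_equal(glandseg:::.lr_at(cfg, 0), 0.0025)
  expect_equal(glandseg:::.lr_at(cfg, 100), 0.2 * 0.0025)
  expect_equal(glandseg:::.lr_at(cfg, 250), 0.2 * 0.0025)  # saturated
  expect_equal(glandseg:::.lr_at(cfg, 50), 0.0025 * 0.6)   # linear midpoint
  expect_equal(glandseg:::.momentum_at(cfg, 0), 0.8)
  expect_equal(glandseg:::.momentum_at(cfg, 25), 0.895)
  expect_equal(glandseg:::.momentum_at(cfg, 50), 0.99)
  expect_equal(glandseg:::.momentum_at(cfg, 200), 0.99)
})

test_that("sliding-window maps equal per-patch forward passes and are normalised", {
  tr <- make_intensity_patches(40, 2L, seed = 3)
  va <- make_intensity_patches(20, 2L, seed = 4)
  cfg <- train_config(batch_size = 20L, max_epochs = 12L, patience = 5L,
                      seed = 11)
  net <- train_network(small_spec("separator"), tr, va, cfg)

  set.seed(5)
  ch <- matrix(runif(100, 0, 255), 10, 10)
  maps <- predict_maps(net, ch)
  expect_identical(dim(maps), c(10L, 10L, 2L))
  expect_lt(max(abs(maps[, , 1] + maps[, , 2] - 1)), 1e-5)

  # oracle: explicit per-patch forward pass over the mirror-padded image
  ps <- net$spec$input_size
  r <- (ps - 1L) / 2L
  padded <- glandseg:::.pad_mirror(ch, r)
  for (i in c(1, 4, 10)) for (j in c(1, 7, 10)) {
    p <- padded[i:(i + ps - 1L), j:(j + ps - 1L)]
    pr <- predict_patches(net, array(p, dim = c(ps, ps, 1)))
    expect_equal(as.vector(pr), maps[i, j, ], tolerance = 1e-12)
  }

  # a constant input yields spatially constant maps
  cmaps <- predict_maps(net, matrix(128, 9, 9))
  expect_lt(diff(range(cmaps[, , 1])), 1e-12)

  expect_error(predict_maps(init_network(small_spec("separator")), ch),
               "untrained")
})
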