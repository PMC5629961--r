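test_that("edge map follows the exponential gradient law", {
  const <- matrix(50, 8, 8)
  expect_equal(compute_edge_map(const), matrix(1, 8, 8))  # e^0 = 1

  # a strong step edge with growing alpha drives g to 0
  step <- matrix(0, 8, 8); step[, 5:8] <- 255
  g1 <- compute_edge_map(step, alpha = 10)
  g2 <- compute_edge_map(step, alpha = 100)
  expect_lt(min(g2), min(g1))
  expect_lt(min(g2), 1e-10)
  expect_true(all(g1 > 0 & g1 <= 1))

  # default parameterisation
  expect_equal(formals(compute_edge_map)$alpha, 10)
  expect_equal(formals(compute_edge_map)$beta, 0.95)
  expect_error(compute_edge_map(const, alpha = -1), "> 0")
})

test_that("weight map applies the confidence-gated logit transform", {
  mk <- function(fg, bg) list(p_fg = matrix(fg, 1, 1), p_bg = matrix(bg, 1, 1))
  expect_equal(compute_weight_map(mk(0.5, 0.5), tau = 0.65)[1, 1], 0)
  expect_equal(compute_weight_map(mk(0.6, 0.4), tau = 0.65)[1, 1], 0)
  # hand-evaluated logit: -(ln .9 - ln .1) = -2.1972...
  expect_equal(compute_weight_map(mk(0.9, 0.1), tau = 0.65)[1, 1],
               -(log(0.9) - log(0.1)), tolerance = 1e-12)
  expect_equal(compute_weight_map(mk(0.9, 0.1), tau = 0.65)[1, 1],
               -2.1972, tolerance = 1e-4)
  expect_equal(compute_weight_map(mk(0.1, 0.9), tau = 0.65)[1, 1],
               log(0.9) - log(0.1), tolerance = 1e-12)
  # clipping keeps certain probabilities finite
  expect_true(is.finite(compute_weight_map(mk(1, 0), tau = 0.5)[1, 1]))
  # sign structure: negative only where foreground dominates
  set.seed(1)
  pfg <- matrix(runif(25), 5, 5)
  w <- compute_weight_map(list(p_fg = pfg, p_bg = 1 - pfg), tau = 0)
  expect_true(all(w[pfg > 0.5] < 0))
  expect_true(all(w[pfg <= 0.5] >= 0))
})

test_that("solver saturates the box under uniform data forcing", {
  g <- matrix(1, 6, 6)
  s1 <- solve_wtv(g, matrix(-2, 6, 6), 0.5)
  expect_equal(s1$u, matrix(1, 6, 6), tolerance = 1e-9)
  s0 <- solve_wtv(g, matrix(2, 6, 6), 0.5)
  expect_equal(s0$u, matrix(0, 6, 6), tolerance = 1e-9)
  expect_true(s1$converged)
})

test_that("dynamic-programming oracle agrees with raw enumeration", {
  set.seed(12)
  for (rep in 1:6) {
    H <- sample(2:3, 1); W <- sample(3:4, 1)
    g <- matrix(runif(H * W, 0.05, 1), H, W)
    w <- matrix(rnorm(H * W, 0, 2), H, W)
    lam <- runif(1, 0.05, 2)
    expect_equal(tv_exhaustive_min(g, w, lam)$energy,
                 brute_force_tv_min(g, w, lam), tolerance = 1e-9)
  }
})

test_that("thresholded solver output attains the exhaustive binary minimum", {
  set.seed(13)
  for (rep in 1:15) {
    H <- sample(4:5, 1); W <- sample(4:5, 1)
    g <- matrix(runif(H * W, 0.05, 1), H, W)
    w <- matrix(rnorm(H * W, 0, 2), H, W)
    lam <- runif(1, 0.05, 2)
    sol <- suppressWarnings(solve_wtv(g, w, lam, max_iters = 5000, tol = 1e-9))
    e_thr <- tv_energy((sol$u >= 0.5) * 1, g, w, lam)
    expect_lte(e_thr, tv_exhaustive_min(g, w, lam)$energy + 1e-6)
  }
})

test_that("energy trace decreases and the (w, lambda) scaling identity holds", {
  set.seed(14)
  g <- matrix(runif(144, 0.2, 1), 12, 12)
  w <- matrix(rnorm(144), 12, 12)
  sol <- suppressWarnings(solve_wtv(g, w, 0.5, max_iters = 400))
  tr <- sol$energy_trace
  # windowed means are non-increasing after the first iterations
  win <- stats::filter(tr, rep(1 / 10, 10), sides = 1)
  win <- win[!is.na(win)]
  expect_true(all(diff(win[-(1:10)]) <= 1e-8))

  # scaling w by c and lambda by 1/c leaves the minimiser unchanged
  c0 <- 3.7
  a <- suppressWarnings(solve_wtv(g, w, 0.5, max_iters = 2000))
  b <- suppressWarnings(solve_wtv(g, w * c0, 0.5 / c0, max_iters = 2000))
  expect_equal(a$u, b$u, tolerance = 1e-4)
})

test_that("binarisation fills holes, enforces min area, and labels instances", {
  u <- matrix(0, 40, 60)
  u[3:27, 3:27] <- 1          # 625 px blob
  u[10:15, 40:55] <- 0.9      # 96 px blob, below a 500 px minimum
  u[12, 12] <- 0              # enclosed hole
  lab <- binarize_and_label(u, min_area = 500)
  expect_equal(max(lab), 1L)
  expect_equal(lab[12, 12], 1L)           # hole filled
  expect_true(all(lab[10:15, 40:55] == 0L))

  # one blob above and one below the area threshold
  u2 <- matrix(0, 40, 80)
  u2[5:28, 5:29] <- 1   # 600 px
  u2[5:24, 50:69] <- 1  # 400 px
  expect_equal(max(binarize_and_label(u2, min_area = 500)), 1L)
  expect_equal(max(binarize_and_label(u2, min_area = 300)), 2L)

  # empty segmentation
  expect_equal(max(binarize_and_label(matrix(0.2, 10, 10))), 0L)

  # post-conditions on random fields: no small objects, no enclosed holes
  set.seed(15)
  for (rep in 1:5) {
    uu <- matrix(runif(900), 30, 30)
    ll <- binarize_and_label(uu, min_area = 20)
    if (max(ll) > 0) {
      expect_true(all(tabulate(ll[ll > 0]) >= 20))
      expect_identical(glandseg:::.fill_holes(ll > 0), ll > 0)
    }
  }
})
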