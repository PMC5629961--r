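test_that("object matching applies the maximum-overlap 50% rule", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L
  lab[7:9, 6:9] <- 2L

  # identical label images: all true positives
  m <- match_objects(lab, lab)
  expect_equal(c(m$TP, m$FP, m$FN), c(2L, 0L, 0L))

  # a hypothesis covering 48% of its best ground-truth object: FP + FN
  gt <- matrix(0L, 10, 10)
  gt[1:5, 1:10] <- 1L            # 50 px object
  seg <- matrix(0L, 10, 10)
  seg[1:3, 1:8] <- 1L            # 24 px -> 48% of gt
  m2 <- match_objects(gt, seg)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0L, 1L, 1L))

  # two hypotheses on one object, 60% and 20%: one TP, one FP, no FN
  gt3 <- matrix(0L, 10, 10); gt3[1:10, 1:5] <- 1L   # 50 px
  seg3 <- matrix(0L, 10, 10)
  seg3[1:6, 1:5] <- 1L   # 30 px = 60%
  seg3[8:9, 1:5] <- 2L   # 10 px = 20%
  m3 <- match_objects(gt3, seg3)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(1L, 1L, 0L))

  expect_error(match_objects(gt3, matrix(0L, 5, 5)), "shape")
})

test_that("match counts partition both object sets on random fixtures", {
  set.seed(20)
  for (rep in 1:8) {
    sc <- generate_scene(scene_config(n_glands = sample(2:4, 1), seed = rep))
    u <- matrix(runif(prod(dim(sc$labels)), 0.3, 0.7), nrow(sc$labels))
    seg <- binarize_and_label(u + (sc$labels > 0) * 0.25, min_area = 50)
    m <- match_objects(sc$labels, seg)
    expect_equal(m$TP + m$FN, length(unique(sc$labels[sc$labels > 0])))
    expect_equal(m$TP + m$FP, max(seg))
  }
})

test_that("detection scores follow the precision/recall/F1 formulas with guards", {
  expect_equal(unname(detection_scores(list(TP = 2, FP = 1, FN = 1))),
               c(2/3, 2/3, 2/3))
  expect_equal(detection_scores(list(TP = 5, FP = 0, FN = 0))[["F1"]], 1)
  expect_equal(detection_scores(list(TP = 0, FP = 3, FN = 2))[["F1"]], 0)
  expect_equal(detection_scores(list(TP = 0, FP = 0, FN = 0))[["F1"]], 0)
})

test_that("Dice coefficient matches its set formula and conventions", {
  G <- matrix(FALSE, 4, 4)
  G[1, 1:3] <- TRUE; G[2, 1:3] <- TRUE                       # |G| = 6
  S <- matrix(FALSE, 4, 4)
  S[1, 1:2] <- TRUE; S[2, 1] <- TRUE; S[3, 4] <- TRUE        # |S| = 4, |G&S| = 3
  expect_equal(dice(G, S), 2 * 3 / (6 + 4))
  expect_equal(dice(G, G), 1)
  disjoint <- matrix(FALSE, 4, 4); disjoint[4, ] <- TRUE
  expect_equal(dice(G, disjoint), 0)
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_true(abs(dice(S, G) - dice(G, S)) < 1e-15)
})

test_that("object-level Dice aggregates weighted max-overlap pairs", {
  lab <- matrix(0L, 8, 8); lab[1:3, 1:4] <- 1L; lab[6:7, 6:7] <- 2L
  expect_equal(object_dice(lab, lab), 1)
  expect_equal(object_dice(lab, matrix(0L, 8, 8)), 0)

  # two-GT / two-seg toy grid, hand-evaluated via the definition
  gt <- matrix(0L, 6, 6)
  gt[1:3, 1:4] <- 1L    # area 12
  gt[5:6, 1:2] <- 2L    # area 4
  seg <- matrix(0L, 6, 6)
  seg[1:3, 2:4] <- 1L   # area 9; overlap with gt1 = 9
  seg[5:6, 2:3] <- 2L   # area 4; overlap with gt2 = 2
  d1 <- 2 * 9 / (12 + 9); d2 <- 2 * 2 / (4 + 4)
  expected <- 0.5 * ((12 / 16) * d1 + (4 / 16) * d2 +
                     (9 / 13) * d1 + (4 / 13) * d2)
  expect_equal(object_dice(gt, seg), expected, tolerance = 1e-12)

  # with one object per image the object level reduces to pixel level
  one_gt <- matrix(0L, 6, 6); one_gt[2:4, 2:5] <- 1L
  one_seg <- matrix(0L, 6, 6); one_seg[3:5, 2:4] <- 1L
  expect_equal(object_dice(one_gt, one_seg),
               dice(one_gt > 0, one_seg > 0), tolerance = 1e-12)
})

test_that("Hausdorff distance equals the brute-force sup-inf evaluation", {
  A <- matrix(c(1, 1), 1, 2); B <- matrix(c(1, 6), 1, 2)
  expect_equal(hausdorff(A, B), 5)
  m <- matrix(FALSE, 5, 5); m[2:3, 2:3] <- TRUE
  expect_equal(hausdorff(m, m), 0)

  set.seed(21)
  for (rep in 1:5) {
    P <- cbind(sample(50, 20, TRUE), sample(50, 20, TRUE))
    Q <- cbind(sample(50, 20, TRUE), sample(50, 20, TRUE))
    expect_equal(hausdorff(P, Q), brute_hausdorff(P, Q), tolerance = 1e-12)
    expect_equal(hausdorff(P, Q), hausdorff(Q, P))
  }
  expect_error(hausdorff(matrix(FALSE, 3, 3), m[1:3, 1:3]), "empty")
})

test_that("object-level Hausdorff mirrors the weighted aggregation", {
  lab <- matrix(0L, 8, 8); lab[1:3, 1:4] <- 1L; lab[6:7, 6:7] <- 2L
  expect_equal(object_hausdorff(lab, lab), 0)

  # hand evaluation on a two-object grid with identical partner pairing
  gt <- matrix(0L, 6, 6); gt[1:3, 1:4] <- 1L; gt[5:6, 1:2] <- 2L
  seg <- matrix(0L, 6, 6); seg[1:3, 2:4] <- 1L; seg[5:6, 2:3] <- 2L
  h1 <- brute_hausdorff(which(gt == 1L, arr.ind = TRUE),
                        which(seg == 1L, arr.ind = TRUE))
  h2 <- brute_hausdorff(which(gt == 2L, arr.ind = TRUE),
                        which(seg == 2L, arr.ind = TRUE))
  expected <- 0.5 * ((12 / 16) * h1 + (4 / 16) * h2 +
                     (9 / 13) * h1 + (4 / 13) * h2)
  expect_equal(object_hausdorff(gt, seg), expected, tolerance = 1e-12)

  # empty segmentation side: undefined
  expect_true(is.na(object_hausdorff(gt, matrix(0L, 6, 6))))
})

test_that("classification metrics reproduce the reference confusion tables", {
  cm <- glas_tissue_confusion()
  a <- classification_metrics(cm$test_a)
  expect_equal(round(a$ACC, 3), 0.983)
  expect_equal(round(a$per_class$PRC[1], 3), 1.000)
  expect_equal(round(a$per_class$REC[1], 3), 0.970)
  expect_equal(round(a$per_class$PRC[2], 3), 0.964)
  expect_equal(round(a$per_class$REC[2], 3), 1.000)
  expect_equal(round(a$per_class$F1[2], 3), 0.982)

  b <- classification_metrics(cm$test_b)
  expect_equal(round(b$ACC, 3), 0.950)
  expect_equal(round(b$per_class$PRC[1], 3), 0.800)
  expect_equal(round(b$per_class$F1[1], 3), 0.889)
  expect_equal(round(b$per_class$REC[2], 3), 0.938)

  # perfect classifier
  p <- classification_metrics(diag(c(10, 10)))
  expect_equal(p$ACC, 1)
  expect_equal(p$per_class$F1, c(1, 1))
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})
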