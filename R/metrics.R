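# GlaS-style evaluation: object matching with the 50% overlap rule, detection
# precision/recall/F1, pixel- and object-level Dice, object-level Hausdorff
# distance, and the 2x2 benign/malignant classification metrics.

#' Match segmented objects to ground-truth objects
#'
#' Each segmented object is associated with the ground-truth object of maximum
#' pixel overlap. A detection counts as a true positive when the overlap
#' fraction reaches `min_overlap` (default 50%); otherwise it is a false
#' positive. Ground-truth objects never claimed by a true positive are false
#' negatives, so `TP + FN` equals the number of ground-truth objects and
#' `TP + FP` the number of segmented objects. The overlap fraction is the
#' intersection divided by the ground-truth object's area by default
#' (`overlap = "gt"`); intersection-over-union is available as
#' `overlap = "iou"`.
#'
#' @param gt `H x W` integer ground-truth label image.
#' @param seg `H x W` integer segmentation label image (same shape).
#' @param min_overlap minimum overlap fraction for a true positive.
#' @param overlap overlap definition, `"gt"` or `"iou"`.
#' @return list of class `"match_result"`: `TP`, `FP`, `FN` counts and a
#'   data.frame `pairs` with one row per segmented object (`seg`, `gt`,
#'   `overlap`, `matched`).
#' @export
match_objects <- function(gt, seg, min_overlap = 0.5,
                          overlap = c("gt", "iou")) {
  overlap <- match.arg(overlap)
  if (!all(dim(gt) == dim(seg)))
    stop("'gt' and 'seg' must have the same shape", call. = FALSE)
  gt_ids <- sort(unique(gt[gt > 0L]))
  seg_ids <- sort(unique(seg[seg > 0L]))
  n_G <- length(gt_ids); n_S <- length(seg_ids)
  if (n_S == 0L)
    return(structure(list(TP = 0L, FP = 0L, FN = n_G,
                          pairs = data.frame(seg = integer(0), gt = integer(0),
                                             overlap = numeric(0),
                                             matched = logical(0))),
                     class = "match_result"))
  inter <- table(factor(gt[seg > 0L | gt > 0L], levels = c(0L, gt_ids)),
                 factor(seg[seg > 0L | gt > 0L], levels = c(0L, seg_ids)))
  inter <- as.matrix(inter)
  gt_area <- tabulate(match(gt[gt > 0L], gt_ids), nbins = n_G)
  seg_area <- tabulate(match(seg[seg > 0L], seg_ids), nbins = n_S)

  pairs <- data.frame(seg = integer(n_S), gt = NA_integer_,
                      overlap = numeric(n_S), matched = FALSE)
  for (si in seq_len(n_S)) {
    col <- inter[-1L, si + 1L]  # intersections with each gt object
    pairs$seg[si] <- seg_ids[si]
    if (n_G == 0L || all(col == 0)) next
    gi <- which.max(col)
    denom <- if (overlap == "gt") gt_area[gi] else
      gt_area[gi] + seg_area[si] - col[gi]
    pairs$gt[si] <- gt_ids[gi]
    pairs$overlap[si] <- col[gi] / denom
  }
  # claim ground-truth objects in order of decreasing overlap; at most one
  # true positive per ground-truth object
  claimed <- logical(n_G)
  for (si in order(pairs$overlap, decreasing = TRUE)) {
    if (is.na(pairs$gt[si]) || pairs$overlap[si] < min_overlap) next
    gi <- match(pairs$gt[si], gt_ids)
    if (!claimed[gi]) { claimed[gi] <- TRUE; pairs$matched[si] <- TRUE }
  }
  TP <- sum(pairs$matched)
  structure(list(TP = TP, FP = n_S - TP, FN = n_G - sum(claimed),
                 pairs = pairs),
            class = "match_result")
}

#' Detection precision, recall and F1
#'
#' `PRC = TP/(TP+FP)`, `REC = TP/(TP+FN)`, `F1 = 2*PRC*REC/(PRC+REC)`, with
#' 0/0 cases returning 0.
#'
#' @param m a `"match_result"` (or a list with TP, FP, FN).
#' @return named numeric vector `c(PRC, REC, F1)`.
#' @export
detection_scores <- function(m) {
  prc <- if (m$TP + m$FP > 0L) m$TP / (m$TP + m$FP) else 0
  rec <- if (m$TP + m$FN > 0L) m$TP / (m$TP + m$FN) else 0
  f1 <- if (prc + rec > 0) 2 * prc * rec / (prc + rec) else 0
  c(PRC = prc, REC = rec, F1 = f1)
}

#' Dice coefficient of two pixel sets
#'
#' `2|G intersect S| / (|G| + |S|)`; two empty sets give 1 by convention.
#'
#' @param G,S logical masks over the same domain.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(G, S) {
  if (!all(dim(G) == dim(S)))
    stop("'G' and 'S' must share a domain", call. = FALSE)
  nG <- sum(G); nS <- sum(S)
  if (nG + nS == 0L) return(1)
  2 * sum(G & S) / (nG + nS)
}

# split a label image into a list of logical masks plus areas/weights
.instances <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  masks <- lapply(ids, function(k) lab == k)
  areas <- vapply(masks, sum, numeric(1))
  list(ids = ids, masks = masks, areas = areas,
       weights = if (length(areas)) areas / sum(areas) else numeric(0))
}

.max_overlap_partner <- function(mask, other_lab) {
  ov <- other_lab[mask]
  ov <- ov[ov > 0L]
  if (length(ov) == 0L) return(NULL)
  as.integer(names(which.max(table(ov))))
}

#' Object-level Dice coefficient
#'
#' Area-weighted two-sided aggregate of per-object Dice values:
#' \deqn{\mathrm{Dice}_{obj} = \tfrac12 \Big[ \sum_i \tilde\omega_i\,
#'   \mathrm{Dice}(\tilde G_i, \tilde S_i) + \sum_i \omega_i\,
#'   \mathrm{Dice}(G_i, S_i) \Big],}
#' where each object is paired with the maximally overlapping object on the
#' other side (an object with no overlap contributes Dice 0) and the weights
#' are the objects' relative areas within their own side.
#'
#' @param gt,seg `H x W` integer label images.
#' @return scalar in \[0, 1\].
#' @export
object_dice <- function(gt, seg) {
  if (!all(dim(gt) == dim(seg)))
    stop("'gt' and 'seg' must have the same shape", call. = FALSE)
  G <- .instances(gt); S <- .instances(seg)
  if (length(G$ids) == 0L && length(S$ids) == 0L) return(1)
  side <- function(a, a_lab, b_lab) {
    if (length(a$ids) == 0L) return(0)
    s <- 0
    for (i in seq_along(a$ids)) {
      partner <- .max_overlap_partner(a$masks[[i]], b_lab)
      d <- if (is.null(partner)) 0 else dice(a$masks[[i]], b_lab == partner)
      s <- s + a$weights[i] * d
    }
    s
  }
  0.5 * (side(G, gt, seg) + side(S, seg, gt))
}

#' Hausdorff distance between two pixel sets
#'
#' Maximum of the two directed sup-inf Euclidean distances between the pixel
#' coordinate sets, in pixel units.
#'
#' @param G,S logical masks (non-empty) or `n x 2` coordinate matrices.
#' @return scalar distance in pixels.
#' @export
hausdorff <- function(G, S) {
  coords <- function(x) {
    if (is.logical(x) || (is.matrix(x) && all(x %in% c(0, 1)) && ncol(x) != 2L))
      which(x != 0, arr.ind = TRUE)
    else as.matrix(x)
  }
  A <- coords(G); B <- coords(S)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("Hausdorff distance is undefined for an empty set", call. = FALSE)
  directed <- function(P, Q) {
    # chunked nearest-neighbour distances to bound memory
    worst <- 0
    chunk <- max(1L, floor(4e6 / nrow(Q)))
    for (s in seq.int(1L, nrow(P), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(P))
      d2 <- outer(P[s:e, 1L], Q[, 1L], "-")^2 + outer(P[s:e, 2L], Q[, 2L], "-")^2
      worst <- max(worst, sqrt(max(apply(d2, 1L, min))))
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

#' Object-level Hausdorff distance
#'
#' Area-weighted two-sided aggregate mirroring [object_dice()], with the
#' Hausdorff distance as the per-pair score. An object with no overlapping
#' partner is scored against the nearest instance on the other side, keeping
#' the aggregate finite while penalising spurious and missed objects. If one
#' side has no objects at all the metric is undefined and `NA` is returned.
#'
#' @param gt,seg `H x W` integer label images.
#' @return scalar distance in pixels, or `NA` when undefined.
#' @export
object_hausdorff <- function(gt, seg) {
  if (!all(dim(gt) == dim(seg)))
    stop("'gt' and 'seg' must have the same shape", call. = FALSE)
  G <- .instances(gt); S <- .instances(seg)
  if (length(G$ids) == 0L || length(S$ids) == 0L) {
    if (length(G$ids) == length(S$ids)) return(0)
    return(NA_real_)
  }
  nearest_instance <- function(mask, other) {
    # instance on the other side with the smallest boundary-to-boundary gap
    pts <- which(mask, arr.ind = TRUE)
    dmin <- vapply(other$masks, function(om) {
      q <- which(om, arr.ind = TRUE)
      min_d <- Inf
      chunk <- max(1L, floor(4e6 / nrow(q)))
      for (s in seq.int(1L, nrow(pts), by = chunk)) {
        e <- min(s + chunk - 1L, nrow(pts))
        d2 <- outer(pts[s:e, 1L], q[, 1L], "-")^2 +
              outer(pts[s:e, 2L], q[, 2L], "-")^2
        min_d <- min(min_d, min(d2))
      }
      min_d
    }, numeric(1))
    which.min(dmin)
  }
  side <- function(a, a_lab, b, b_lab) {
    s <- 0
    for (i in seq_along(a$ids)) {
      partner <- .max_overlap_partner(a$masks[[i]], b_lab)
      pj <- if (is.null(partner)) nearest_instance(a$masks[[i]], b)
            else match(partner, b$ids)
      s <- s + a$weights[i] * hausdorff(a$masks[[i]], b$masks[[pj]])
    }
    s
  }
  0.5 * (side(G, gt, S, seg) + side(S, seg, G, gt))
}

#' Benign/malignant classification metrics from a confusion matrix
#'
#' Overall accuracy `ACC = tr(M) / sum(M)` plus per-class precision, recall
#' and F1, treating each class in turn as positive. Rows of `M` are predicted
#' classes, columns are ground truth.
#'
#' @param M 2 x 2 (or k x k) non-negative count matrix.
#' @return list with `ACC` and a data.frame `per_class` (class, PRC, REC, F1).
#' @export
classification_metrics <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || any(M < 0))
    stop("'M' must be a square non-negative count matrix", call. = FALSE)
  if (sum(M) == 0) stop("confusion matrix is empty", call. = FALSE)
  classes <- rownames(M)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(M)))
  per <- do.call(rbind, lapply(seq_len(nrow(M)), function(k) {
    tp <- M[k, k]; fp <- sum(M[k, -k]); fn <- sum(M[-k, k])
    sc <- detection_scores(list(TP = tp, FP = fp, FN = fn))
    data.frame(class = classes[k], PRC = sc[["PRC"]], REC = sc[["REC"]],
               F1 = sc[["F1"]])
  }))
  list(ACC = sum(diag(M)) / sum(M), per_class = per)
}

#' Evaluate a set of segmentations against ground truth
#'
#' Computes per-image detection and segmentation metrics and the dataset
#' mean (SD) summary, following the convention of reporting object-level
#' metrics as mean and standard deviation over individual images.
#'
#' @param gt_list,seg_list lists of aligned integer label images.
#' @param min_overlap true-positive overlap threshold (default 0.5).
#' @return list with `per_image` (data.frame: image, PRC, REC, F1, Dice_obj,
#'   HD_obj) and `summary` (data.frame: metric, mean, sd).
#' @export
evaluate_segmentations <- function(gt_list, seg_list, min_overlap = 0.5) {
  stopifnot(length(gt_list) == length(seg_list))
  rows <- lapply(seq_along(gt_list), function(i) {
    m <- match_objects(gt_list[[i]], seg_list[[i]], min_overlap)
    sc <- detection_scores(m)
    data.frame(image = i, PRC = sc[["PRC"]], REC = sc[["REC"]], F1 = sc[["F1"]],
               Dice_obj = object_dice(gt_list[[i]], seg_list[[i]]),
               HD_obj = object_hausdorff(gt_list[[i]], seg_list[[i]]))
  })
  per_image <- do.call(rbind, rows)
  metrics <- c("PRC", "REC", "F1", "Dice_obj", "HD_obj")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_image[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_image[[m]], na.rm = TRUE), numeric(1)))
  list(per_image = per_image, summary = summary)
}

#' Reference confusion matrices for GlaS benign/malignant classification
#'
#' The 2 x 2 confusion matrices (rows = predicted class, columns = ground
#' truth) reported for the two GlaS challenge test sets by the CNN + weighted
#' TV pipeline this package implements: test A spans 60 images, test B 20.
#' They serve as worked inputs for [classification_metrics()] in examples,
#' tests and the acceptance script.
#'
#' Note: applying the stated precision/recall/F1 formulas to the test A matrix
#' gives a benign F1 of 2(1.0)(0.970)/(1.0 + 0.970) = 0.985; the commonly
#' quoted benign F1 of 0.976 for that set is not consistent with those
#' formulas and is therefore not reproduced by this package.
#'
#' @return named list of two 2 x 2 matrices, `test_a` and `test_b`, with
#'   dimnames `predicted` x `truth`.
#' @export
glas_tissue_confusion <- function() {
  dn <- list(predicted = c("benign", "malignant"),
             truth = c("benign", "malignant"))
  list(test_a = matrix(c(32L, 1L, 0L, 27L), 2L, 2L, dimnames = dn),
       test_b = matrix(c(4L, 0L, 1L, 15L), 2L, 2L, dimnames = dn))
}
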