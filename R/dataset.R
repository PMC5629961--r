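# Training-data construction: the four-class label transform, separator
# ground-truth rasterization, balanced patch sampling and rotation
# augmentation.

#' Transform object labels into the four-class training labels
#'
#' Converts an integer-labelled object image (0 = background, k > 0 = gland k)
#' together with its image-level malignancy flag into the four-class raster
#' used to train the object classifier: benign background (0), benign gland
#' (1), malignant background (2), malignant gland (3). A benign image thus
#' contains only values \{0, 1\} and a malignant one only \{2, 3\}; the gland
#' classes \{1, 3\} reproduce exactly the nonzero pixels of the input.
#'
#' @param labels `H x W` integer matrix of object labels (non-negative).
#' @param malignant logical image-level malignancy flag (required).
#' @return `H x W` integer matrix with values in \{0, 1, 2, 3\}.
#' @export
transform_labels <- function(labels, malignant) {
  .assert_raster(labels * 1)
  if (missing(malignant) || is.null(malignant) || is.na(malignant))
    stop("the image-level 'malignant' flag is required", call. = FALSE)
  if (any(labels < 0)) stop("object labels must be non-negative", call. = FALSE)
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- 1L
  if (isTRUE(malignant)) out <- out + 2L
  out
}

#' Rasterize gland-separator polylines into a binary mask
#'
#' Separating structures are annotated as polylines following the narrow
#' stroma corridors between adjacent gland borders. Each segment is rasterized
#' at sub-pixel steps, and the resulting one-pixel trace is dilated to the
#' requested thickness with a disc brush.
#'
#' @param polylines list of point sequences; each element an `n x 2` matrix of
#'   `(x, y)` = `(col, row)` coordinates, 1-based. Points outside the image are
#'   clipped with a warning.
#' @param shape integer `c(H, W)` output size.
#' @param thickness line thickness in pixels (default 3).
#' @return binary `H x W` matrix (0/1).
#' @export
rasterize_separators <- function(polylines, shape, thickness = 3L) {
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  mask <- matrix(0L, H, W)
  if (length(polylines) == 0L) return(mask)
  clipped <- FALSE
  for (pl in polylines) {
    pl <- as.matrix(pl)
    if (nrow(pl) == 0L) next
    if (any(pl[, 1L] < 1 | pl[, 1L] > W | pl[, 2L] < 1 | pl[, 2L] > H))
      clipped <- TRUE
    if (nrow(pl) == 1L) {
      x <- pl[1L, 1L]; y <- pl[1L, 2L]
    } else {
      x <- numeric(0); y <- numeric(0)
      for (s in seq_len(nrow(pl) - 1L)) {
        n <- max(2L, ceiling(2 * max(abs(pl[s + 1L, ] - pl[s, ]))) + 1L)
        t <- seq(0, 1, length.out = n)
        x <- c(x, pl[s, 1L] + t * (pl[s + 1L, 1L] - pl[s, 1L]))
        y <- c(y, pl[s, 2L] + t * (pl[s + 1L, 2L] - pl[s, 2L]))
      }
    }
    r <- pmin(pmax(round(y), 1L), H)
    c <- pmin(pmax(round(x), 1L), W)
    mask[cbind(r, c)] <- 1L
  }
  if (clipped)
    warning("separator polyline points outside the image were clipped")
  if (thickness > 1L) {
    brush <- EBImage::makeBrush(as.integer(thickness), shape = "disc")
    mask <- .from_eb(EBImage::dilate(.to_eb(mask), brush))
    storage.mode(mask) <- "integer"
  }
  mask
}

#' Sample a class-balanced patch dataset
#'
#' Draws `per_class` square patches per class, centred at pixels sampled
#' uniformly (without replacement) from each class of the label raster.
#' Centres closer than half a patch to the border use mirror padding. When a
#' class has fewer eligible pixels than `per_class`, sampling falls back to
#' with-replacement and a warning is issued.
#'
#' @param channel `H x W` structure channel in `[0, 255]`.
#' @param labels `H x W` integer class raster aligned with `channel`.
#' @param per_class patches per class; the training default for the full-scale
#'   setup is 125000, tests use far smaller values.
#' @param patch_size odd patch edge length (default 101).
#' @param seed optional RNG seed for reproducible sampling.
#' @param classes class values to sample (default: all values present).
#' @return object of class `"patch_dataset"`: list with `patches`
#'   (`patch_size x patch_size x n` array), `labels` (class value per patch),
#'   `centers` (`n x 2` matrix of row/col), `classes`, `per_class`,
#'   `patch_size`, `seed`.
#' @export
sample_balanced_patches <- function(channel, labels, per_class = 125000L,
                                    patch_size = 101L, seed = NULL,
                                    classes = NULL) {
  .assert_raster(channel)
  if (!all(dim(channel) == dim(labels)))
    stop("'labels' must be aligned with 'channel'", call. = FALSE)
  if (per_class < 1L) stop("'per_class' must be >= 1", call. = FALSE)
  if (patch_size %% 2L != 1L) stop("'patch_size' must be odd", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(as.vector(labels)))

  centers <- .with_seed(seed, {
    do.call(rbind, lapply(classes, function(cl) {
      elig <- which(labels == cl)
      if (length(elig) == 0L)
        stop(sprintf("no eligible pixels for class %s", cl), call. = FALSE)
      if (length(elig) < per_class) {
        warning(sprintf(
          "class %s has only %d eligible pixels for %d requested patches; sampling with replacement",
          cl, length(elig), per_class))
        idx <- sample(elig, per_class, replace = TRUE)
      } else {
        idx <- sample(elig, per_class, replace = FALSE)
      }
      cbind(arrayInd(idx, dim(labels)), cl)
    }))
  })

  r <- (patch_size - 1L) %/% 2L
  padded <- .pad_mirror(channel, r)
  n <- nrow(centers)
  patches <- array(0, dim = c(patch_size, patch_size, n))
  off <- seq.int(0L, patch_size - 1L)
  for (i in seq_len(n)) {
    patches[, , i] <- padded[centers[i, 1L] + off, centers[i, 2L] + off]
  }
  structure(list(patches = patches,
                 labels = centers[, 3L],
                 centers = centers[, 1:2, drop = FALSE],
                 classes = classes, per_class = as.integer(per_class),
                 patch_size = as.integer(patch_size), seed = seed),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("patch_dataset: %d patches (%d per class x %d classes), %dx%d px\n",
              length(x$labels), x$per_class, length(x$classes),
              x$patch_size, x$patch_size))
  invisible(x)
}

#' Combine patch datasets sampled from different images
#'
#' Concatenates several `"patch_dataset"` objects (e.g. benign-scene patches
#' carrying classes 0/1 with malignant-scene patches carrying 2/3) into one
#' training set. Patch sizes must agree.
#'
#' @param ... `"patch_dataset"` objects.
#' @return a `"patch_dataset"` covering the union of classes.
#' @export
combine_patch_datasets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0, all(vapply(sets, inherits, logical(1), "patch_dataset")))
  ps <- unique(vapply(sets, function(s) s$patch_size, integer(1)))
  if (length(ps) != 1L) stop("patch sizes differ", call. = FALSE)
  patches <- array(unlist(lapply(sets, `[[`, "patches")),
                   dim = c(ps, ps, sum(vapply(sets, function(s) length(s$labels), integer(1)))))
  structure(list(patches = patches,
                 labels = unlist(lapply(sets, `[[`, "labels")),
                 centers = do.call(rbind, lapply(sets, `[[`, "centers")),
                 classes = sort(unique(unlist(lapply(sets, `[[`, "classes")))),
                 per_class = sets[[1L]]$per_class,
                 patch_size = ps, seed = sets[[1L]]$seed),
            class = "patch_dataset")
}

#' Rotation augmentation of a patch
#'
#' Returns `count` rotated copies of a square patch at angles `step_degrees,
#' 2*step_degrees, ..., count*step_degrees` (the unrotated original is not
#' included). Rotation is about the patch centre with bilinear interpolation
#' and mirror boundary handling, so the centre pixel -- whose label the patch
#' carries -- is preserved. The defaults (9 copies every 36 degrees) implement
#' the rotation-invariance augmentation used to enrich separator foreground
#' samples.
#'
#' @param patch square numeric matrix.
#' @param count number of rotated copies (default 9).
#' @param step_degrees angular step in degrees (default 36).
#' @return list of `count` rotated patches; attribute `angles` records the
#'   rotation angles in degrees.
#' @export
augment_rotations <- function(patch, count = 9L, step_degrees = 36) {
  .assert_raster(patch)
  if (nrow(patch) != ncol(patch)) stop("'patch' must be square", call. = FALSE)
  angles <- step_degrees * seq_len(count)
  out <- lapply(angles, function(a) .rotate_patch(patch, a))
  attr(out, "angles") <- angles
  out
}

# Rotate a square patch about its centre; inverse mapping, bilinear sampling,
# mirror boundary.
.rotate_patch <- function(patch, angle_deg) {
  n <- nrow(patch)
  theta <- angle_deg * pi / 180
  ct <- cos(theta); st <- sin(theta)
  c0 <- (n + 1) / 2
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  dy <- g$r - c0; dx <- g$c - c0
  # inverse rotation of output coords into source coords
  sx <- ct * dx + st * dy + c0
  sy <- -st * dx + ct * dy + c0
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;  fy <- sy - y0
  ix0 <- .mirror_index(x0, n); ix1 <- .mirror_index(x0 + 1, n)
  iy0 <- .mirror_index(y0, n); iy1 <- .mirror_index(y0 + 1, n)
  v <- (1 - fy) * ((1 - fx) * patch[cbind(iy0, ix0)] + fx * patch[cbind(iy0, ix1)]) +
       fy       * ((1 - fx) * patch[cbind(iy1, ix0)] + fx * patch[cbind(iy1, ix1)])
  matrix(v, n, n)
}
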