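# Synthetic H&E-like scenes with full ground truth, plus simulated classifier
# outputs, so the refinement, TV segmentation, classification and evaluation
# stages are all testable without any external dataset. Scenes emulate the
# tissue components of a gland image: a bright lumen disk wrapped in a dark
# epithelial (hematoxylin-rich) ring, embedded in textured eosin-pink stroma.
# Malignant scenes perturb the gland boundary into non-convex shapes and
# partially occlude the lumen.

#' Configuration for a synthetic gland scene
#'
#' @param size integer `c(H, W)` canvas size in pixels.
#' @param n_glands number of glands to place.
#' @param radius_range `c(min, max)` base gland radius in pixels.
#' @param min_gap minimum boundary gap between non-touching glands (pixels).
#' @param touching_fraction fraction of glands arranged in close ("touching")
#'   pairs separated only by a thin stroma corridor.
#' @param touch_gap boundary gap of a touching pair, in pixels.
#' @param malignant logical; malignant scenes use irregular, non-convex gland
#'   boundaries and partially occluded lumina.
#' @param noise_sd standard deviation of the additive Gaussian texture noise
#'   on each RGB channel (intensity levels).
#' @param lumen_frac lumen radius as a fraction of the gland radius.
#' @param sep_gap_threshold boundary gap (pixels) below which the stroma
#'   corridor between two glands is annotated as a separating structure.
#' @param sep_thickness thickness of the separator annotation (pixels).
#' @param seed RNG seed; identical seeds give bit-identical scenes.
#' @return list of class `"scene_config"`.
#' @export
scene_config <- function(size = c(200L, 200L), n_glands = 4L,
                         radius_range = c(16, 26), min_gap = 16,
                         touching_fraction = 0, touch_gap = 2,
                         malignant = FALSE, noise_sd = 8,
                         lumen_frac = 0.55, sep_gap_threshold = 10,
                         sep_thickness = 5L, seed = NULL) {
  stopifnot(all(radius_range > 0), touching_fraction >= 0,
            touching_fraction <= 1, lumen_frac > 0, lumen_frac < 1)
  structure(list(size = as.integer(size), n_glands = as.integer(n_glands),
                 radius_range = radius_range, min_gap = min_gap,
                 touching_fraction = touching_fraction, touch_gap = touch_gap,
                 malignant = isTRUE(malignant), noise_sd = noise_sd,
                 lumen_frac = lumen_frac,
                 sep_gap_threshold = sep_gap_threshold,
                 sep_thickness = as.integer(sep_thickness), seed = seed),
            class = "scene_config")
}

# Radial boundary function r(theta) of a gland: near-circular for benign,
# strongly perturbed (non-convex) for malignant. Glands placed as a touching
# pair are rendered as exact circles so the stroma corridor between them has
# exactly the configured width.
.gland_radius_fn <- function(r0, malignant, paired = FALSE) {
  if (paired) return(function(theta) rep(r0, length(theta)))
  if (!malignant) {
    a <- stats::runif(1, 0, 0.06); ph <- stats::runif(1, 0, 2 * pi)
    k <- sample(2:3, 1)
    function(theta) r0 * (1 + a * sin(k * theta + ph))
  } else {
    a1 <- stats::runif(1, 0.15, 0.3); k1 <- sample(3:5, 1)
    a2 <- stats::runif(1, 0.05, 0.12); k2 <- sample(6:9, 1)
    p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
    function(theta) r0 * (1 + a1 * sin(k1 * theta + p1) + a2 * sin(k2 * theta + p2))
  }
}

# distance from every pixel to the nearest pixel of a mask
.distance_to <- function(mask) {
  inv <- matrix(1, nrow(mask), ncol(mask))
  inv[mask] <- 0
  .from_eb(EBImage::distmap(.to_eb(inv)))
}

#' Generate a synthetic H&E-like gland scene
#'
#' Renders `n_glands` glands (lumen + epithelial ring) over textured stroma,
#' returning the RGB image, the integer object-label image, the binary
#' separator ground truth, and the malignancy flag. Touching pairs are placed
#' with a boundary gap of `touch_gap` pixels; the separator ground truth is
#' the thin stroma corridor between any two glands whose boundary gap is
#' below `sep_gap_threshold`, dilated to `sep_thickness`. Generation is
#' deterministic under the config seed; an infeasible packing (too many or
#' too large glands) raises an error after bounded retries.
#'
#' @param config a [scene_config()].
#' @return list of class `"synthetic_scene"`: `image` (`H x W x 3`, 0-255),
#'   `labels` (`H x W` integer), `separator` (`H x W` 0/1), `malignant`,
#'   `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  .with_seed(config$seed, {
    H <- config$size[1L]; W <- config$size[2L]
    n <- config$n_glands
    n_pairs <- floor(n * config$touching_fraction / 2)

    # boundary perturbation can extend a gland beyond its base radius, so
    # non-touching separation requirements use an inflated radius
    infl <- if (config$malignant) 1.45 else 1.08
    margin <- function(r0) r0 * infl + 2
    place <- function(centers, radii, r0, near = NULL, gap = NULL) {
      for (try in 1:300) {
        if (is.null(near)) {
          ct <- c(stats::runif(1, margin(r0), H - margin(r0)),
                  stats::runif(1, margin(r0), W - margin(r0)))
        } else {
          ang <- stats::runif(1, 0, 2 * pi)
          d <- radii[near] + r0 + gap
          ct <- centers[near, ] + d * c(cos(ang), sin(ang))
          if (any(ct < margin(r0)) || ct[1L] > H - margin(r0) ||
              ct[2L] > W - margin(r0)) next
        }
        ok <- TRUE
        if (nrow(centers) > 0) {
          dd <- sqrt(rowSums((centers - matrix(ct, nrow(centers), 2,
                                               byrow = TRUE))^2))
          req <- (radii + r0) * infl + config$min_gap
          if (!is.null(near)) req[near] <- radii[near] + r0 + gap
          ok <- all(dd >= req - 1e-9)
        }
        if (ok) return(ct)
      }
      NULL
    }
    pack_all <- function() {
      centers <- matrix(0, 0, 2); radii <- numeric(0)
      paired <- logical(0)
      n_paired <- 0L
      for (i in seq_len(n)) {
        r0 <- stats::runif(1, config$radius_range[1L], config$radius_range[2L])
        is_pair <- FALSE
        if (n_paired < n_pairs * 2L && i %% 2L == 0L) {
          ct <- place(centers, radii, r0, near = i - 1L, gap = config$touch_gap)
          if (!is.null(ct)) { n_paired <- n_paired + 2L; is_pair <- TRUE }
        } else {
          ct <- place(centers, radii, r0)
        }
        if (is.null(ct)) return(NULL)
        centers <- rbind(centers, ct)
        radii <- c(radii, r0)
        paired <- c(paired, is_pair)
        if (is_pair) paired[i - 1L] <- TRUE
      }
      list(centers = centers, radii = radii, paired = paired)
    }
    packing <- NULL
    for (attempt in 1:10) {
      packing <- pack_all()
      if (!is.null(packing)) break
    }
    if (is.null(packing))
      stop("infeasible gland packing; reduce n_glands or radii", call. = FALSE)
    centers <- packing$centers; radii <- packing$radii
    paired <- packing$paired

    labels <- matrix(0L, H, W)
    lumen <- matrix(FALSE, H, W)
    rr <- row(labels); cc <- col(labels)
    for (k in seq_len(n)) {
      rf <- .gland_radius_fn(radii[k], config$malignant, paired[k])
      dy <- rr - centers[k, 1L]; dx <- cc - centers[k, 2L]
      dist <- sqrt(dy^2 + dx^2)
      theta <- atan2(dx, dy)
      rb <- rf(theta)
      inside <- dist <= rb
      labels[inside & labels == 0L] <- k
      lum <- dist <= rb * config$lumen_frac
      if (config$malignant) {
        # occlude a random angular sector of the lumen with epithelium
        a0 <- stats::runif(1, 0, 2 * pi)
        wid <- stats::runif(1, pi / 2, 4 * pi / 3)
        dtheta <- (theta - a0) %% (2 * pi)
        lum <- lum & !(dtheta < wid)
      }
      lumen <- lumen | (lum & inside)
    }

    # separator ground truth: thin stroma corridor between close gland pairs
    separator <- matrix(0L, H, W)
    gmasks <- lapply(seq_len(n), function(k) labels == k)
    dmaps <- lapply(gmasks, .distance_to)
    bg <- labels == 0L
    for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
      gapab <- min((dmaps[[a]] + dmaps[[b]])[bg])
      if (gapab < config$sep_gap_threshold) {
        corridor <- bg & (dmaps[[a]] + dmaps[[b]] <= gapab + 1.2) &
          dmaps[[a]] <= config$sep_gap_threshold &
          dmaps[[b]] <= config$sep_gap_threshold
        separator[corridor] <- 1L
      }
    }
    if (any(separator > 0L) && config$sep_thickness > 1L) {
      brush <- EBImage::makeBrush(config$sep_thickness, shape = "disc")
      separator <- .from_eb(EBImage::dilate(.to_eb(separator), brush))
      storage.mode(separator) <- "integer"
      separator[labels > 0L] <- 0L  # separators live in the stroma
    }

    # render: stroma / epithelium / lumen in H&E-like colours + texture noise.
    # Malignant tissue is rendered with hyperchromatic (hematoxylin-denser)
    # epithelium and denser, desmoplastic-looking stroma, so benign and
    # malignant variants differ in local staining statistics as well as in
    # gland morphology.
    if (config$malignant) {
      col_stroma <- c(214, 148, 186)
      col_epith <- c(82, 50, 122)
    } else {
      col_stroma <- c(231, 169, 202)
      col_epith <- c(130, 92, 168)
    }
    col_lumen <- c(246, 243, 246)
    img <- array(0, dim = c(H, W, 3L))
    epith <- labels > 0L & !lumen
    # malignant stroma additionally carries scattered dark nuclei
    # (desmoplastic/inflammatory infiltrate), a local texture cue that
    # survives contrast normalisation
    nuclei <- matrix(FALSE, H, W)
    if (config$malignant) {
      n_nuc <- round(sum(labels == 0L) * 0.01)
      nr <- sample.int(H, n_nuc, replace = TRUE)
      nc <- sample.int(W, n_nuc, replace = TRUE)
      nuclei[cbind(nr, nc)] <- TRUE
      nuclei <- .from_eb(EBImage::dilate(.to_eb(nuclei * 1),
                                         EBImage::makeBrush(3L, "disc"))) > 0
      nuclei <- nuclei & labels == 0L
    }
    for (ch in 1:3) {
      plane <- matrix(col_stroma[ch], H, W)
      plane[epith] <- col_epith[ch]
      plane[labels > 0L & lumen] <- col_lumen[ch]
      plane[nuclei] <- col_epith[ch]
      plane <- plane + stats::rnorm(H * W, 0, config$noise_sd)
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }

    structure(list(image = img, labels = labels, separator = separator,
                   malignant = config$malignant, config = config),
              class = "synthetic_scene")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulated classifier probability maps from ground-truth labels
#'
#' Builds the four-class one-hot probability maps implied by an object-label
#' image and its malignancy flag, optionally softened by Gaussian blur
#' (emulating the spatial smoothness of CNN predictions) and corrupted by
#' flip noise (a fraction of pixels replaced by a random one-hot class), then
#' renormalised per pixel. The separator map is the (optionally blurred)
#' separator ground truth. These fixtures let the refinement, TV segmentation
#' and classification stages run exactly as they would on network outputs.
#'
#' @param labels `H x W` integer object-label image.
#' @param malignant image-level malignancy flag.
#' @param flip_noise fraction of pixels whose class is flipped, in `[0, 1)`.
#' @param blur Gaussian blur sigma in pixels (0 = none).
#' @param separator optional binary separator mask to convert into a
#'   separator probability map.
#' @param seed RNG seed for the flip noise.
#' @return list with `maps` (`H x W x 4`, per-pixel sum 1) and `separator`
#'   (`H x W` in `[0, 1]`, or `NULL`).
#' @export
generate_probability_fixtures <- function(labels, malignant, flip_noise = 0,
                                          blur = 0, separator = NULL,
                                          seed = NULL) {
  four <- transform_labels(labels, malignant)
  H <- nrow(four); W <- ncol(four)
  maps <- array(0, dim = c(H, W, 4L))
  for (l in 0:3) maps[, , l + 1L][four == l] <- 1

  maps <- .with_seed(seed, {
    if (flip_noise > 0) {
      flip <- which(matrix(stats::runif(H * W), H, W) < flip_noise)
      cls <- sample.int(4L, length(flip), replace = TRUE)
      for (l in 1:4) {
        plane <- maps[, , l]
        plane[flip] <- as.numeric(cls == l)
        maps[, , l] <- plane
      }
    }
    maps
  })
  if (blur > 0)
    for (l in 1:4)
      maps[, , l] <- .from_eb(EBImage::gblur(.to_eb(maps[, , l]), sigma = blur))
  tot <- maps[, , 1L] + maps[, , 2L] + maps[, , 3L] + maps[, , 4L]
  for (l in 1:4) maps[, , l] <- maps[, , l] / tot

  sep_map <- NULL
  if (!is.null(separator)) {
    sep_map <- separator * 1
    if (blur > 0) {
      sep_map <- .from_eb(EBImage::gblur(.to_eb(sep_map), sigma = blur))
      if (max(sep_map) > 0) sep_map <- sep_map / max(sep_map) * max(separator)
    }
    sep_map <- pmin(pmax(sep_map, 0), 1)
  }
  list(maps = maps, separator = sep_map)
}
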