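# Preprocessing of raw H&E RGB images into the normalized structure channel
# consumed by the pixel classifiers: colour deconvolution -> keep the first
# (hematoxylin) channel -> CLAHE -> optional half-resolution downsampling.

#' Default H&E stain matrix ("H&E 2" preset)
#'
#' Unit-norm optical-density vectors for hematoxylin and eosin, taken from the
#' widely used "H&E 2" preset of G. Landini's colour-deconvolution plugin for
#' Fiji/ImageJ. The third stain vector, unspecified in the preset, is the
#' normalised cross product of the first two, giving a complete invertible
#' basis. Rows are stains, columns are R, G, B optical densities.
#'
#' @return a 3 x 3 numeric matrix with unit-norm rows.
#' @export
he2_stain_matrix <- function() {
  h <- c(0.49015734, 0.76897085, 0.41040173)
  e <- c(0.04615336, 0.84206840, 0.53739250)
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- rbind(h / sqrt(sum(h^2)), e / sqrt(sum(e^2)), r / sqrt(sum(r^2)))
  dimnames(m) <- list(c("hematoxylin", "eosin", "residual"), c("R", "G", "B"))
  m
}

.normalize_stain_matrix <- function(stain_matrix) {
  if (!is.matrix(stain_matrix) || !all(dim(stain_matrix) == c(3L, 3L)))
    stop("'stain_matrix' must be a 3 x 3 matrix of stain OD vectors", call. = FALSE)
  norms <- sqrt(rowSums(stain_matrix^2))
  if (any(norms == 0))
    stop("stain matrix has a zero row; provide three independent stain vectors",
         call. = FALSE)
  m <- stain_matrix / norms
  if (abs(det(m)) < 1e-8)
    stop("stain matrix is singular after unit normalization", call. = FALSE)
  m
}

#' Colour deconvolution of an H&E RGB image
#'
#' Separates an RGB image into per-stain density channels by inverting the
#' Beer-Lambert optical-density mixing model (the Ruifrok-Johnston scheme):
#' optical densities `OD = -log10(I / 255)` are expressed in the basis of the
#' unit-norm stain vectors, so each output channel is the amount of one stain
#' at each pixel. Intensities are clamped to a minimum of 0.5 before the log so
#' that pure black pixels stay finite; the round trip through
#' [reconstruct_rgb()] then agrees with the input to within one intensity
#' level.
#'
#' @param image `H x W x 3` array, intensities in `[0, 255]`.
#' @param stain_matrix 3 x 3 matrix of stain OD vectors (rows = stains);
#'   rows are unit-normalised internally. Default [he2_stain_matrix()].
#' @return an object of class `"stain_density"`: a list with `channels`
#'   (`H x W x 3` stain densities) and the normalised `stain_matrix`.
#' @seealso [structure_channel()], [reconstruct_rgb()]
#' @export
color_deconvolve <- function(image, stain_matrix = he2_stain_matrix()) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("'image' must be an H x W x 3 RGB array", call. = FALSE)
  m <- .normalize_stain_matrix(stain_matrix)
  d <- dim(image)
  od <- -log10(pmax(image, 0.5) / 255)
  dim(od) <- c(d[1L] * d[2L], 3L)
  dens <- od %*% solve(m)
  dim(dens) <- d
  structure(list(channels = dens, stain_matrix = m), class = "stain_density")
}

#' Reconstruct an RGB image from stain densities
#'
#' Forward Beer-Lambert model: `I = 255 * 10^-(D %*% M)`, clipped to
#' `[0, 255]`. Inverse of [color_deconvolve()] up to intensity clamping.
#'
#' @param sd a `"stain_density"` object.
#' @return `H x W x 3` RGB array.
#' @export
reconstruct_rgb <- function(sd) {
  stopifnot(inherits(sd, "stain_density"))
  d <- dim(sd$channels)
  dens <- sd$channels
  dim(dens) <- c(d[1L] * d[2L], 3L)
  od <- dens %*% sd$stain_matrix
  img <- pmin(pmax(255 * 10^(-od), 0), 255)
  dim(img) <- d
  img
}

#' Extract a single-stain structure channel
#'
#' Keeps one deconvolved stain channel and maps its density back to an 8-bit
#' transmittance image (`255 * 10^-density`, dark = densely stained). The first
#' (hematoxylin) channel carries most of the glandular structure in H&E
#' sections and is the default; the remaining channels carry little contrast
#' and are discarded.
#'
#' @param sd a `"stain_density"` object.
#' @param channel index of the stain channel to keep (default 1).
#' @return `H x W` matrix in `[0, 255]` with attribute `scale = 1`.
#' @export
structure_channel <- function(sd, channel = 1L) {
  stopifnot(inherits(sd, "stain_density"))
  ch <- pmin(pmax(255 * 10^(-sd$channels[, , channel]), 0), 255)
  attr(ch, "scale") <- 1
  ch
}

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE to a single-channel raster in `[0, 255]` to normalise staining
#' contrast and illumination across images. Thin wrapper around
#' [EBImage::clahe()].
#'
#' @param channel `H x W` numeric matrix in `[0, 255]`.
#' @param clip_limit positive contrast clip limit (default 2).
#' @param tile_grid integer `c(rows, cols)` of equalization tiles (default
#'   `c(8, 8)`). Must not exceed the image dimensions.
#' @return equalized `H x W` matrix in `[0, 255]`, `scale` attribute preserved.
#' @export
apply_clahe <- function(channel, clip_limit = 2, tile_grid = c(8L, 8L)) {
  .assert_raster(channel)
  if (length(tile_grid) != 2L || any(tile_grid < 1L))
    stop("'tile_grid' must be two positive integers (rows, cols)", call. = FALSE)
  if (tile_grid[1L] > nrow(channel) || tile_grid[2L] > ncol(channel))
    stop("CLAHE tile grid larger than the image", call. = FALSE)
  if (clip_limit <= 0) stop("'clip_limit' must be positive", call. = FALSE)
  # the equalizer needs dims divisible by the tile grid: mirror-pad and crop
  H <- nrow(channel); W <- ncol(channel)
  Hp <- as.integer(ceiling(H / tile_grid[1L]) * tile_grid[1L])
  Wp <- as.integer(ceiling(W / tile_grid[2L]) * tile_grid[2L])
  x <- channel[.mirror_index(seq_len(Hp), H), .mirror_index(seq_len(Wp), W),
               drop = FALSE]
  out <- EBImage::clahe(.to_eb(x / 255),
                        nx = as.integer(tile_grid[2L]),
                        ny = as.integer(tile_grid[1L]),
                        limit = clip_limit)
  res <- pmin(pmax(.from_eb(out)[seq_len(H), seq_len(W), drop = FALSE] * 255,
                   0), 255)
  attr(res, "scale") <- attr(channel, "scale")
  res
}

#' Preprocess a raw H&E RGB image
#'
#' Full preprocessing chain: colour deconvolution, extraction of the first
#' stain channel, CLAHE, and (optionally) downsampling to the half-resolution
#' working scale at which the pixel classifiers operate. The full-resolution
#' channel is retained because the edge map of the TV segmentation is computed
#' at the original scale.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param stain_matrix stain OD basis, see [color_deconvolve()].
#' @param channel stain channel to keep (default 1 = hematoxylin).
#' @param clip_limit,tile_grid CLAHE parameters, see [apply_clahe()].
#' @param half_resolution downsample to half resolution for classification
#'   (default `TRUE`, area averaging).
#' @return list with `full` (CLAHE channel at scale 1) and `half` (working
#'   channel, scale 0.5, or `NULL` when `half_resolution = FALSE`).
#' @export
preprocess_image <- function(image, stain_matrix = he2_stain_matrix(),
                             channel = 1L, clip_limit = 2,
                             tile_grid = c(8L, 8L), half_resolution = TRUE) {
  sd <- color_deconvolve(image, stain_matrix)
  full <- apply_clahe(structure_channel(sd, channel), clip_limit, tile_grid)
  attr(full, "scale") <- 1
  half <- NULL
  if (half_resolution) {
    half <- resample(full, factor = 0.5, mode = "area")
    attr(half, "scale") <- 0.5
  }
  list(full = full, half = half)
}
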