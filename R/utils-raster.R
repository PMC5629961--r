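# Internal raster helpers.
#
# Convention used throughout the package: a single-channel raster is a plain
# numeric matrix with dim c(H, W), indexed [row, col] = [y, x]; an RGB image
# is an array with dim c(H, W, 3) and intensities in [0, 255]. EBImage stores
# images transposed (x first), so every call into EBImage goes through
# .to_eb() / .from_eb().

.to_eb <- function(m) EBImage::Image(t(m))

.from_eb <- function(img) t(EBImage::imageData(img))

#' @noRd
.assert_raster <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix (H x W raster)", name), call. = FALSE)
  invisible(x)
}

# Map arbitrary integer indices onto 1..n by mirror (symmetric) reflection,
# so padding radii larger than the image are handled.
.mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j))
}

# Mirror-pad a matrix by r pixels on every side.
.pad_mirror <- function(m, r) {
  ri <- .mirror_index(seq.int(1L - r, nrow(m) + r), nrow(m))
  ci <- .mirror_index(seq.int(1L - r, ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Evaluate a scoped RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Resample a raster or label image
#'
#' Rescales a single-channel raster (or an `H x W x C` array, channel-wise) to
#' `floor(dim * factor)` pixels. Intensity images should use `"bilinear"` (the
#' mode used to upsample probability maps back to full resolution) or `"area"`
#' (block averaging, used when downsampling to the half-resolution working
#' scale); label images must use `"nearest"`, which never invents label values.
#'
#' @param x numeric matrix (`H x W`) or array (`H x W x C`).
#' @param factor positive scalar scale factor; output dims are
#'   `floor(dim(x) * factor)`. Ignored when `dims` is given.
#' @param dims optional integer `c(H, W)` target size, overriding `factor`.
#' @param mode one of `"bilinear"`, `"nearest"`, `"area"`. `"area"` performs
#'   exact block averaging when `1/factor` is a whole number and the image
#'   divides evenly; otherwise it falls back to bilinear interpolation.
#' @return resampled raster of the same type as the input.
#' @examples
#' r <- matrix(runif(775 * 522), 775, 522)
#' dim(resample(r, 0.5, mode = "area"))  # 387 x 261
#' @export
resample <- function(x, factor = NULL, dims = NULL,
                     mode = c("bilinear", "nearest", "area")) {
  mode <- match.arg(mode)
  if (is.array(x) && length(dim(x)) == 3L) {
    ch <- lapply(seq_len(dim(x)[3L]), function(k)
      resample(x[, , k], factor = factor, dims = dims, mode = mode))
    return(array(unlist(ch), dim = c(dim(ch[[1L]]), length(ch))))
  }
  .assert_raster(x)
  if (is.null(dims)) {
    if (is.null(factor) || !is.numeric(factor) || factor <= 0)
      stop("'factor' must be a positive scalar", call. = FALSE)
    dims <- pmax(1L, as.integer(floor(dim(x) * factor)))
  }
  dims <- as.integer(dims)
  if (all(dims == dim(x))) return(x)

  if (mode == "area") {
    # exact block mean when the source divides evenly into the target
    bh <- dim(x)[1L] / dims[1L]
    bw <- dim(x)[2L] / dims[2L]
    if (bh >= 1 && bw >= 1 &&
        abs(bh - round(bh)) < 1e-9 && abs(bw - round(bw)) < 1e-9) {
      bh <- round(bh); bw <- round(bw)
      a <- array(x, dim = c(bh, dims[1L], bw, dims[2L]))
      return(apply(a, c(2L, 4L), mean))
    }
    mode <- "bilinear"
  }
  filt <- if (mode == "nearest") "none" else "bilinear"
  out <- EBImage::resize(.to_eb(x), w = dims[2L], h = dims[1L], filter = filt)
  m <- .from_eb(out)
  if (mode == "nearest") {
    # defensive: nearest must preserve the label alphabet exactly
    storage.mode(m) <- storage.mode(x)
  }
  m
}

# Connected-component labelling of a binary mask. Foreground uses 4-connectivity
# (EBImage::bwlabel); 8-connectivity (needed for background/hole analysis) is
# done by iterative minimum-label propagation, which is exact and fast at the
# image sizes this package works with.
.label_components <- function(mask, connectivity = 4L) {
  .assert_raster(mask * 1)
  if (connectivity == 4L) {
    lab <- .from_eb(EBImage::bwlabel(.to_eb(mask * 1)))
    storage.mode(lab) <- "integer"
    return(lab)
  }
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  repeat {
    padded <- matrix(big, H + 2L, W + 2L)
    l0 <- lab; l0[!mask] <- big
    padded[2:(H + 1L), 2:(W + 1L)] <- l0
    nb <- pmin(
      padded[1:H, 2:(W + 1L)], padded[3:(H + 2L), 2:(W + 1L)],
      padded[2:(H + 1L), 1:W], padded[2:(H + 1L), 3:(W + 2L)],
      padded[1:H, 1:W], padded[1:H, 3:(W + 2L)],
      padded[3:(H + 2L), 1:W], padded[3:(H + 2L), 3:(W + 2L)])
    new <- lab
    upd <- mask & nb < lab
    new[upd] <- nb[upd]
    if (identical(new, lab)) break
    lab <- new
  }
  # compact label ids to 1..n
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

# Fill enclosed background holes: background regions (8-connected) that do not
# touch the image border become foreground.
.fill_holes <- function(mask) {
  bg <- !mask
  lab <- .label_components(bg, connectivity = 8L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- bg & !(lab %in% border)
  mask | hole
}
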