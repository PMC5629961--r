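# End-to-end orchestration: preprocess -> pixel classification (both nets) ->
# map refinement -> upsampling -> weighted-TV segmentation -> instance
# labelling, plus whole-image tissue classification, the TV parameter grid
# search, and config/IO plumbing.

#' Segment an image from probability maps
#'
#' The tail of the pipeline shared by network predictions and simulated
#' fixtures: combines the four class maps with the separator map at the
#' classification scale, bilinearly upsamples the figure/ground maps to the
#' full-resolution structure channel, derives the confidence-gated logit
#' weight map and the edge map, solves the weighted-TV problem and labels the
#' thresholded result.
#'
#' @param maps `h x w x 4` class probability array (classification scale).
#' @param separator optional `h x w` separator probability map (`NULL` for
#'   the ablation without separator refinement).
#' @param channel_full `H x W` structure channel at full resolution (used
#'   for the edge map and as the target size of the upsampling).
#' @param params a [tv_params()].
#' @return list with `labels` (`H x W` instance labels), `u` (relaxed
#'   segmentation), `p_fg`, `p_bg` (full resolution), `tv` (the
#'   `"tv_solution"`).
#' @export
segment_from_maps <- function(maps, separator = NULL, channel_full,
                              params = tv_params()) {
  fgbg <- combine_maps(maps, separator)
  dims <- dim(channel_full)
  p_fg <- resample(fgbg$p_fg, dims = dims, mode = "bilinear")
  p_bg <- resample(fgbg$p_bg, dims = dims, mode = "bilinear")
  w <- compute_weight_map(list(p_fg = p_fg, p_bg = p_bg), tau = params$tau)
  g <- compute_edge_map(channel_full, alpha = params$alpha, beta = params$beta)
  tv <- solve_wtv(g, w, lambda = params$lambda, max_iters = params$max_iters,
                  tol = params$tol, tv_norm = params$tv_norm)
  labels <- binarize_and_label(tv$u, threshold = 0.5,
                               min_area = params$min_area)
  list(labels = labels, u = tv$u, p_fg = p_fg, p_bg = p_bg, tv = tv)
}

#' Run the full segmentation + classification pipeline on one image
#'
#' Preprocesses the RGB image (colour deconvolution, CLAHE, half-resolution
#' working scale), predicts the four-class and separator probability maps
#' with the trained networks, refines and upsamples them, solves the
#' weighted-TV segmentation at full resolution, and classifies the whole
#' image as benign or malignant from the half-resolution class maps.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param object_net trained `"network"` of the object variant.
#' @param separator_net trained separator `"network"`, or `NULL` to run the
#'   ablation without separator refinement.
#' @param params a [tv_params()].
#' @param stain_matrix stain basis for the colour deconvolution.
#' @param half_resolution classify at half resolution (default `TRUE`).
#' @param stride sliding-window stride for map prediction.
#' @return list of class `"pipeline_result"`: `labels`, `decision` (a
#'   `"tissue_decision"`), `maps`, `separator_map`, `u`, `p_fg`, `p_bg`.
#' @export
run_pipeline <- function(image, object_net, separator_net = NULL,
                         params = tv_params(),
                         stain_matrix = he2_stain_matrix(),
                         half_resolution = TRUE, stride = 1L) {
  pre <- preprocess_image(image, stain_matrix,
                          half_resolution = half_resolution)
  work <- if (half_resolution) pre$half else pre$full
  maps <- predict_maps(object_net, work, stride = stride)
  sep <- if (!is.null(separator_net))
    predict_maps(separator_net, work, stride = stride)[, , 2L] else NULL
  seg <- segment_from_maps(maps, sep, pre$full, params)
  decision <- classify_tissue(maps)
  structure(c(seg, list(decision = decision, maps = maps,
                        separator_map = sep)),
            class = "pipeline_result")
}

#' Grid search over the TV parameters
#'
#' Evaluates every combination of `alphas`, `betas` and `lambdas` on a set of
#' cases, scoring the binarised segmentation against the ground-truth gland
#' mask with the pixel-level Dice coefficient. Both the per-image mean Dice
#' and the micro-averaged (all pixels pooled) Dice are reported; the argmax
#' uses the per-image mean. Default ranges are the tuning ranges
#' `alpha in [0.5, 15]`, `beta in [0.35, 0.95]`, `lambda in [0.01, 10]`.
#'
#' @param cases list of cases, each a list with `channel` (full-resolution
#'   structure channel), `p_fg`, `p_bg` (full-resolution figure/ground maps)
#'   and `gt_mask` (logical ground-truth gland mask).
#' @param alphas,betas,lambdas numeric grids; the defaults take a small
#'   number of points spanning the tuning ranges.
#' @param params base [tv_params()] supplying tau and solver settings.
#' @return list with `best` (a `tv_params` at the argmax), `table`
#'   (data.frame: alpha, beta, lambda, mean_dice, micro_dice).
#' @export
grid_search_tv <- function(cases,
                           alphas = c(0.5, 5, 10, 15),
                           betas = c(0.35, 0.65, 0.95),
                           lambdas = c(0.01, 0.1, 1, 10),
                           params = tv_params()) {
  if (length(alphas) == 0L || length(betas) == 0L || length(lambdas) == 0L)
    stop("empty parameter grid", call. = FALSE)
  grid <- expand.grid(alpha = alphas, beta = betas, lambda = lambdas)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    inter <- 0; tot <- 0; dices <- numeric(length(cases))
    for (ci in seq_along(cases)) {
      cs <- cases[[ci]]
      w <- compute_weight_map(list(p_fg = cs$p_fg, p_bg = cs$p_bg),
                              tau = params$tau)
      g <- compute_edge_map(cs$channel, alpha = grid$alpha[i],
                            beta = grid$beta[i])
      tv <- solve_wtv(g, w, lambda = grid$lambda[i],
                      max_iters = params$max_iters, tol = params$tol,
                      tv_norm = params$tv_norm)
      seg <- tv$u >= 0.5
      dices[ci] <- dice(cs$gt_mask, seg)
      inter <- inter + sum(cs$gt_mask & seg)
      tot <- tot + sum(cs$gt_mask) + sum(seg)
    }
    c(mean_dice = mean(dices),
      micro_dice = if (tot > 0) 2 * inter / tot else 1)
  })
  tab <- cbind(grid, do.call(rbind, res))
  best_i <- which.max(tab$mean_dice)
  best <- params
  best$alpha <- tab$alpha[best_i]
  best$beta <- tab$beta[best_i]
  best$lambda <- tab$lambda[best_i]
  list(best = best, table = tab)
}

#' Tune the confidence threshold tau
#'
#' Sweeps tau over the candidate set (by default from 0.5 in steps of 0.15)
#' with the other TV parameters fixed, scoring per-image mean pixel Dice.
#'
#' @param cases as in [grid_search_tv()].
#' @param taus candidate thresholds.
#' @param params base [tv_params()].
#' @return list with `best` (tv_params at the argmax) and `table`.
#' @export
tune_tau <- function(cases, taus = c(0.5, 0.65, 0.8, 0.95),
                     params = tv_params()) {
  res <- vapply(taus, function(tau) {
    mean(vapply(cases, function(cs) {
      w <- compute_weight_map(list(p_fg = cs$p_fg, p_bg = cs$p_bg), tau = tau)
      g <- compute_edge_map(cs$channel, params$alpha, params$beta)
      tv <- solve_wtv(g, w, lambda = params$lambda,
                      max_iters = params$max_iters, tol = params$tol,
                      tv_norm = params$tv_norm)
      dice(cs$gt_mask, tv$u >= 0.5)
    }, numeric(1)))
  }, numeric(1))
  best <- params
  best$tau <- taus[which.max(res)]
  list(best = best, table = data.frame(tau = taus, mean_dice = res))
}

#' Read a run configuration file
#'
#' YAML (or JSON) config with sections `preprocess`, `tv`, `training`;
#' missing entries fall back to the package defaults.
#'
#' @param path path to the YAML config file.
#' @return list with `preprocess` (list), `tv` (a `tv_params`), `training`
#'   (a `train_config`), `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pre_defaults <- list(channel = 1L, clip_limit = 2, tile_grid = c(8L, 8L),
                       half_resolution = TRUE)
  pre <- utils::modifyList(pre_defaults, cfg$preprocess %||% list())
  tv <- do.call(tv_params, cfg$tv %||% list())
  tr <- do.call(train_config, cfg$training %||% list())
  list(preprocess = pre, tv = tv, training = tr, seed = cfg$seed %||% NULL)
}

#' Read an RGB or label image from disk
#'
#' PNG/TIFF/JPEG rasters via EBImage; intensities are returned on the 0-255
#' scale (label images as integers).
#'
#' @param path file path.
#' @param kind `"rgb"`, `"gray"` or `"labels"`.
#' @return `H x W x 3` array, `H x W` matrix, or integer label matrix.
#' @export
read_image <- function(path, kind = c("rgb", "gray", "labels")) {
  kind <- match.arg(kind)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (kind == "rgb") {
    if (length(d) < 3L) stop("expected a colour image", call. = FALSE)
    arr <- aperm(EBImage::imageData(img)[, , 1:3], c(2L, 1L, 3L)) * 255
    return(arr)
  }
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) >= 3L) dat <- dat[, , 1L]
  m <- t(dat)
  if (kind == "gray") return(m * 255)
  lab <- round(m * 65535)
  storage.mode(lab) <- "integer"
  lab
}

#' Write a label image (16-bit PNG) or probability raster to disk
#'
#' @param x integer label matrix or numeric raster in `[0, 1]`.
#' @param path output path (`.png` for labels, `.tif` for float rasters).
#' @return `path`, invisibly.
#' @export
write_label_image <- function(x, path) {
  if (max(x) > 65535) stop("label values exceed 16-bit range", call. = FALSE)
  EBImage::writeImage(.to_eb(x / 65535), path, bits.per.sample = 16L)
  invisible(path)
}
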