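# Fusion of the object classifier's four probability maps with the separator
# map into the figure/ground maps that drive the TV segmentation.

#' Combine object and separator probability maps into figure/ground maps
#'
#' The foreground map sums the two gland classes and subtracts the separator
#' probability, clamped at 0; the background map sums the two background
#' classes and adds the separator probability, clamped at 1:
#' \deqn{p_{fg} = \max\{(I_{C_1} + I_{C_3}) - S,\; 0\}, \qquad
#'       p_{bg} = \min\{(I_{C_0} + I_{C_2}) + S,\; 1\}.}
#' Subtracting the separator emphasises gland borders and prevents adjacent
#' glands from merging in the subsequent segmentation. Running without a
#' separator model (`separator = NULL`, i.e. `S = 0`) reproduces the
#' unrefined ablation variant.
#'
#' @param maps `H x W x 4` array of object-class probability maps
#'   (benign background, benign gland, malignant background, malignant gland).
#' @param separator optional `H x W` separator probability map in `[0, 1]`.
#' @return list of class `"figure_ground"` with matrices `p_fg` and `p_bg`,
#'   both in `[0, 1]`; the `scale` attribute of `maps` is carried over.
#' @export
combine_maps <- function(maps, separator = NULL) {
  if (!is.array(maps) || length(dim(maps)) != 3L || dim(maps)[3L] != 4L)
    stop("'maps' must be an H x W x 4 probability array", call. = FALSE)
  S <- if (is.null(separator)) 0 else {
    if (!all(dim(separator) == dim(maps)[1:2]))
      stop("separator map shape does not match the class maps", call. = FALSE)
    separator
  }
  p_fg <- pmax(maps[, , 2L] + maps[, , 4L] - S, 0)
  p_bg <- pmin(maps[, , 1L] + maps[, , 3L] + S, 1)
  structure(list(p_fg = p_fg, p_bg = p_bg, scale = attr(maps, "scale")),
            class = "figure_ground")
}
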