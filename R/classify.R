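# Whole-image benign/malignant decision from the object classifier's maps.

#' Classify a whole image as benign or malignant
#'
#' Averages the per-pixel class probabilities over the image domain:
#' \deqn{\bar P(\mathrm{benign}) = \frac{1}{|\Omega|} \sum_x I_{C_0}(x) + I_{C_1}(x),}
#' and analogously for malignant with \eqn{C_2, C_3}; the larger of the two
#' is the decision, and its value is reported as the decision confidence over
#' the entire image. An exact tie resolves deterministically to benign (a
#' message is emitted). The spatial mean makes the decision invariant to
#' pixel permutation and to tiling of the image, and (up to boundary effects
#' of interpolation) to the resolution of the maps, so the half-resolution
#' classifier maps are used directly.
#'
#' @param maps `H x W x 4` array of per-pixel class probabilities.
#' @return list of class `"tissue_decision"`: `class` (`"benign"` or
#'   `"malignant"`), `malignant` (logical), `p_benign`, `p_malignant`,
#'   `confidence`.
#' @export
classify_tissue <- function(maps) {
  if (!is.array(maps) || length(dim(maps)) != 3L || dim(maps)[3L] != 4L)
    stop("'maps' must be an H x W x 4 probability array", call. = FALSE)
  p_benign <- mean(maps[, , 1L] + maps[, , 2L])
  p_malignant <- mean(maps[, , 3L] + maps[, , 4L])
  if (p_benign == p_malignant)
    message("tissue classification tie; resolving to benign")
  malignant <- p_malignant > p_benign
  structure(list(class = if (malignant) "malignant" else "benign",
                 malignant = malignant,
                 p_benign = p_benign, p_malignant = p_malignant,
                 confidence = max(p_benign, p_malignant)),
            class = "tissue_decision")
}

#' @export
print.tissue_decision <- function(x, ...) {
  cat(sprintf("tissue decision: %s (confidence %.3f; benign %.3f, malignant %.3f)\n",
              x$class, x$confidence, x$p_benign, x$p_malignant))
  invisible(x)
}
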