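#' Z-score normalize an image
#'
#' Centers and scales the pixel intensities by the image mean and the
#' population standard deviation (divisor N, not N-1). A zero-variance
#' (constant) image yields an all-zero output with the `degenerate` flag set
#' rather than an error.
#'
#' @param img a [GrayImage] with at least 2 pixels.
#' @return a [RealImage]; for any non-constant input its mean is 0 and its
#'   population standard deviation 1 up to floating-point error.
#' @examples
#' z <- zscoreNormalize(GrayImage(matrix(c(0L, 2L, 4L, 6L), 2, 2)))
#' range(pixels(z))
#' @export
zscoreNormalize <- function(img) {
  stopifnot(is(img, "GrayImage"))
  px <- pixels(img)
  if (length(px) < 2) stop("z-score normalization needs at least 2 pixels")
  m <- mean(px)
  s <- sqrt(mean((px - m)^2))  # population SD
  if (s == 0)
    return(new("RealImage", pixels = matrix(0, nrow(px), ncol(px)),
               degenerate = TRUE))
  new("RealImage", pixels = (px - m) / s, degenerate = FALSE)
}

#' Re-quantize a real-valued image to integer gray levels
#'
#' Min-max affine map onto `[0, R-1]`, rounded half-up. A constant input
#' maps to level 0 everywhere. This carries z-scored images back into the
#' integer level domain that the energy-curve contrast stage operates on.
#'
#' @param img a [RealImage] (or a finite numeric matrix).
#' @param levels target gray-level count R (default 256).
#' @return a [GrayImage]; for non-constant input the full range `{0, R-1}`
#'   is attained.
#' @export
requantize <- function(img, levels = 256) {
  px <- if (is(img, "RealImage")) pixels(img) else as.matrix(img)
  stopifnot(all(is.finite(px)), levels >= 2)
  lo <- min(px); hi <- max(px)
  if (hi == lo)
    return(GrayImage(matrix(0L, nrow(px), ncol(px)), levels = levels))
  out <- floor((px - lo) / (hi - lo) * (levels - 1) + 0.5)
  GrayImage(out, levels = levels)
}
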