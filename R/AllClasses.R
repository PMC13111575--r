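#' @import methods
NULL

#' GrayImage: a 2-D integer-intensity image
#'
#' The central container of the package: a matrix of non-negative integer
#' gray levels together with the declared number of levels `R` (256 for
#' 8-bit input, 65536 for 16-bit). Coordinates are (row, column), 0-based,
#' row 0 at the top; all window and distance arithmetic in the filtering
#' code uses this convention.
#'
#' @slot pixels integer matrix, every value in `[0, levels - 1]`.
#' @slot levels number of representable gray levels (at least 2).
#'
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", levels = "numeric"),
  prototype(pixels = matrix(0L, 1, 1), levels = 256)
)

setValidity("GrayImage", function(object) {
  px <- object@pixels
  R <- object@levels
  msg <- character()
  if (length(R) != 1 || is.na(R) || R < 2)
    msg <- c(msg, "levels must be a single number >= 2")
  if (!is.numeric(px) || length(dim(px)) != 2)
    msg <- c(msg, "pixels must be a 2-D numeric matrix")
  else {
    if (nrow(px) < 1 || ncol(px) < 1)
      msg <- c(msg, "image must have at least one row and one column")
    if (anyNA(px) || any(!is.finite(px)))
      msg <- c(msg, "pixels must be finite")
    else {
      if (any(px != round(px)))
        msg <- c(msg, "pixels must be integer-valued")
      if (min(px) < 0 || max(px) > R - 1)
        msg <- c(msg, sprintf("pixel values must lie in [0, %d]", as.integer(R - 1)))
    }
  }
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a 2-D \{0,1\} lesion mask
#'
#' @slot pixels matrix of 0/1 values; when paired with a [GrayImage] it must
#'   have the same shape.
#'
#' @export
setClass("BinaryMask", representation(pixels = "matrix"))

setValidity("BinaryMask", function(object) {
  px <- object@pixels
  if (!is.numeric(px) && !is.logical(px)) return("pixels must be numeric or logical")
  if (length(dim(px)) != 2) return("pixels must be a 2-D matrix")
  if (anyNA(px)) return("mask must not contain NA")
  if (!all(px %in% c(0, 1))) return("mask values must be strictly 0 or 1")
  TRUE
})

#' RealImage: a real-valued image (z-score domain)
#'
#' Holds the output of Z-score normalization before re-quantization to
#' integer levels. `degenerate` records the zero-variance case (constant
#' input), in which the output is all zeros by convention.
#'
#' @slot pixels matrix of finite reals.
#' @slot degenerate logical flag set when the source image had zero variance.
#'
#' @export
setClass("RealImage",
  representation(pixels = "matrix", degenerate = "logical"),
  prototype(degenerate = FALSE)
)

setValidity("RealImage", function(object) {
  px <- object@pixels
  if (!is.numeric(px) || length(dim(px)) != 2) return("pixels must be a 2-D numeric matrix")
  if (anyNA(px) || any(!is.finite(px))) return("pixels must be finite")
  TRUE
})

#' WindowPolicy: bounds for the adaptive filter window
#'
#' The adaptive median filter grows its window toward bright artifacts; the
#' policy pins the odd lower bound (never below 3x3), the odd upper cap
#' `sDis`, and the cap used when no artifact was detected at all.
#'
#' @slot uMin odd integer >= 3, the smallest allowed window side.
#' @slot sDis odd integer >= uMin, the largest allowed window side.
#' @slot defaultCapNoSpots odd integer cap used when the spot list is empty.
#'
#' @export
setClass("WindowPolicy",
  representation(uMin = "numeric", sDis = "numeric", defaultCapNoSpots = "numeric"),
  prototype(uMin = 3, sDis = 9, defaultCapNoSpots = 9)
)

setValidity("WindowPolicy", function(object) {
  msg <- character()
  odd <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x %% 2 == 1
  if (!odd(object@uMin) || object@uMin < 3)
    msg <- c(msg, "uMin must be an odd integer >= 3")
  if (!odd(object@sDis)) msg <- c(msg, "sDis must be an odd integer")
  if (!odd(object@defaultCapNoSpots) || object@defaultCapNoSpots < 3)
    msg <- c(msg, "defaultCapNoSpots must be an odd integer >= 3")
  if (length(msg) == 0 && object@sDis < object@uMin)
    msg <- c(msg, "sDis must be >= uMin")
  if (length(msg)) msg else TRUE
})

#' EnergyCurve: per-gray-level spatial energy
#'
#' A spatially aware alternative to the histogram: for each level `l` the
#' image is thresholded into a +/-1 indicator field and the (negated)
#' neighbor agreement is accumulated, so levels at which the thresholded
#' image has many spatial transitions carry high energy. The curve drives
#' the contrast-enhancement transfer function.
#'
#' @slot values non-negative vector of length `levels`; the last entry is 0
#'   because no pixel exceeds the top level.
#' @slot d neighborhood radius (Chebyshev), >= 1.
#' @slot f exponent of the inverse-distance pair weight, in `[1, 3]`.
#' @slot levels number of gray levels R.
#'
#' @export
setClass("EnergyCurve",
  representation(values = "numeric", d = "numeric", f = "numeric", levels = "numeric")
)

setValidity("EnergyCurve", function(object) {
  msg <- character()
  if (length(object@values) != object@levels)
    msg <- c(msg, "values must have length equal to levels")
  if (any(object@values < -1e-9))
    msg <- c(msg, "energy values must be non-negative")
  n <- length(object@values)
  if (n > 0 && abs(object@values[n]) > 1e-9)
    msg <- c(msg, "energy at the top level must be zero")
  if (object@d < 1 || object@d != round(object@d))
    msg <- c(msg, "d must be an integer >= 1")
  if (object@f < 1 || object@f > 3)
    msg <- c(msg, "f must lie in [1, 3]")
  if (length(msg)) msg else TRUE
})

#' ClippedCurve: clipped energy curve
#'
#' @slot values vector of length `levels`, each entry `min(original, clipThreshold)`.
#' @slot clipThreshold the clipping level, mean + median of the raw curve.
#' @slot degenerate set when the raw curve was all zero (constant image).
#' @slot levels number of gray levels R.
#'
#' @export
setClass("ClippedCurve",
  representation(values = "numeric", clipThreshold = "numeric",
                 degenerate = "logical", levels = "numeric"),
  prototype(degenerate = FALSE)
)

setValidity("ClippedCurve", function(object) {
  msg <- character()
  if (length(object@values) != object@levels)
    msg <- c(msg, "values must have length equal to levels")
  if (!object@degenerate && length(object@values) &&
      max(object@values) > object@clipThreshold + 1e-9)
    msg <- c(msg, "values must not exceed the clip threshold")
  if (length(msg)) msg else TRUE
})

#' BandPartition: tri-band split of the gray-level axis
#'
#' The level axis `[0, R-1]` is split into a lower band `[0, loLow]`, a mid
#' band `[loLow+1, loHigh]` and an upper band `[loHigh+1, R-1]` from the
#' energy-weighted spread of the clipped curve; each band is later remapped
#' onto its own output interval.
#'
#' @slot loLow,loHigh band boundaries, `0 <= loLow < loHigh <= R-1`.
#' @slot stdW energy-weighted intensity spread used to place the boundaries.
#' @slot lMin,lMax minimum and maximum level present in the source image.
#' @slot levels number of gray levels R.
#' @slot fallback TRUE when the spread rule collapsed and energy-mass
#'   terciles were used instead.
#'
#' @export
setClass("BandPartition",
  representation(loLow = "numeric", loHigh = "numeric", stdW = "numeric",
                 lMin = "numeric", lMax = "numeric", levels = "numeric",
                 fallback = "logical"),
  prototype(fallback = FALSE)
)

setValidity("BandPartition", function(object) {
  msg <- character()
  R <- object@levels
  if (object@loLow < 0 || object@loLow >= object@loHigh || object@loHigh > R - 1)
    msg <- c(msg, "band boundaries must satisfy 0 <= loLow < loHigh <= R-1")
  if (length(msg)) msg else TRUE
})

#' TransferFunction: per-level output remapping
#'
#' @slot mapping vector of length `levels`: output level for each input
#'   level, each in `[0, R-1]`, non-decreasing within each band.
#' @slot levels number of gray levels R.
#'
#' @export
setClass("TransferFunction",
  representation(mapping = "numeric", levels = "numeric")
)

setValidity("TransferFunction", function(object) {
  msg <- character()
  if (length(object@mapping) != object@levels)
    msg <- c(msg, "mapping must have length equal to levels")
  if (length(object@mapping) &&
      (min(object@mapping) < 0 || max(object@mapping) > object@levels - 1))
    msg <- c(msg, "mapped levels must lie in [0, R-1]")
  if (length(msg)) msg else TRUE
})
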