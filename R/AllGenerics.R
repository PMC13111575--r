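#' Pixel matrix of an image-like object
#'
#' @param x a [GrayImage], [BinaryMask] or [RealImage].
#' @return the underlying matrix (integer levels for `GrayImage`, 0/1 for
#'   `BinaryMask`, reals for `RealImage`).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "RealImage", function(x) x@pixels)

#' Number of representable gray levels
#'
#' @param x a [GrayImage] or derived curve/transfer object.
#' @return the declared level count R (256 for 8-bit, 65536 for 16-bit).
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname nLevels
#' @export
setMethod("nLevels", "GrayImage", function(x) x@levels)

#' @rdname nLevels
#' @export
setMethod("nLevels", "EnergyCurve", function(x) x@levels)

#' @rdname nLevels
#' @export
setMethod("nLevels", "TransferFunction", function(x) x@levels)

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))

#' @export
setMethod("dim", "RealImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  px <- object@pixels
  cat(sprintf("GrayImage: %d x %d, R = %s, range [%d, %d]\n",
              nrow(px), ncol(px), format(object@levels),
              as.integer(min(px)), as.integer(max(px))))
})

setMethod("show", "BinaryMask", function(object) {
  px <- object@pixels
  cat(sprintf("BinaryMask: %d x %d, %d foreground pixels\n",
              nrow(px), ncol(px), as.integer(sum(px))))
})

setMethod("show", "EnergyCurve", function(object) {
  cat(sprintf("EnergyCurve: R = %d, d = %d, f = %g, total energy %.4g\n",
              as.integer(object@levels), as.integer(object@d), object@f,
              sum(object@values)))
})

setMethod("show", "BandPartition", function(object) {
  cat(sprintf(
    "BandPartition: [0,%d] | [%d,%d] | [%d,%d]%s (StD = %.3f)\n",
    as.integer(object@loLow), as.integer(object@loLow) + 1L,
    as.integer(object@loHigh), as.integer(object@loHigh) + 1L,
    as.integer(object@levels) - 1L,
    if (object@fallback) " [tercile fallback]" else "", object@stdW))
})

setMethod("show", "TransferFunction", function(object) {
  cat(sprintf("TransferFunction: R = %d, output range [%d, %d]\n",
              as.integer(object@levels), as.integer(min(object@mapping)),
              as.integer(max(object@mapping))))
})

#' Construct a GrayImage
#'
#' @param pixels integer-valued matrix in `[0, levels - 1]`.
#' @param levels declared gray-level count R (default 256).
#' @return a validated [GrayImage].
#' @examples
#' img <- GrayImage(matrix(0:15, 4, 4))
#' dim(img)
#' @export
GrayImage <- function(pixels, levels = 256) {
  px <- as.matrix(pixels)
  if (is.numeric(px) && !anyNA(px) && any(px != round(px)))
    stop("pixels must be integer-valued")
  attributes(px) <- list(dim = dim(px))
  storage.mode(px) <- if (levels <= .Machine$integer.max) "integer" else "double"
  new("GrayImage", pixels = px, levels = as.numeric(levels))
}

#' Construct a BinaryMask
#'
#' @param pixels matrix of 0/1 (or logical) values.
#' @return a validated [BinaryMask].
#' @export
BinaryMask <- function(pixels) {
  px <- as.matrix(pixels)
  storage.mode(px) <- "integer"
  new("BinaryMask", pixels = px)
}

#' Construct a WindowPolicy
#'
#' @param uMin odd lower window bound (>= 3; the filter never drops below
#'   3x3).
#' @param sDis odd upper window cap; defaults to `uMin` when smaller.
#' @param defaultCapNoSpots odd cap used when no light spot was detected.
#' @return a validated [WindowPolicy].
#' @export
WindowPolicy <- function(uMin = 3, sDis = 9, defaultCapNoSpots = 9) {
  new("WindowPolicy", uMin = uMin, sDis = max(sDis, uMin),
      defaultCapNoSpots = defaultCapNoSpots)
}
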