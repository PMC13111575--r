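# round half up (deterministic level rounding throughout the contrast stage)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Compute the spatial energy curve of an image
#'
#' For each gray level `l` the image is thresholded into a +/-1 indicator
#' field (`+1` where the pixel exceeds `l`). The energy at `l` is the negated
#' sum of neighbor products plus the total pair count, with each ordered
#' neighbor pair (Chebyshev distance at most `d`, clipped at the border)
#' weighted by `(1 / chebyshev distance)^f`. Equivalently, each disagreeing
#' pair contributes twice its weight, so `E(l) >= 0` always, `E(l) = 0`
#' exactly when the thresholded field is constant, and `E(R-1) = 0` since no
#' pixel exceeds the top level.
#'
#' The implementation sweeps every neighbor offset once and accumulates each
#' pair's contribution over the level range `[min(v_p, v_q), max(v_p, v_q))`
#' with a difference array, which is exact and avoids the per-level loop.
#'
#' @param img a [GrayImage].
#' @param d neighborhood radius in Chebyshev distance (default 1, the 8
#'   immediate neighbors).
#' @param f exponent of the inverse-distance pair weight, in `[1, 3]`
#'   (default 1; with `d = 1` all weights are then 1, the classic curve).
#' @return an [EnergyCurve] of length R.
#' @examples
#' ec <- computeEnergyCurve(GrayImage(matrix(c(0L, 1L, 1L, 0L), 2, 2), levels = 2))
#' ec@values  # c(16, 0)
#' @export
computeEnergyCurve <- function(img, d = 1, f = 1) {
  stopifnot(is(img, "GrayImage"), d >= 1, d == round(d), f >= 1, f <= 3)
  px <- pixels(img)
  R <- nLevels(img)
  nr <- nrow(px); nc <- ncol(px)
  delta <- numeric(R)
  for (dy in -d:d) {
    for (dx in -d:d) {
      if (dy == 0 && dx == 0) next
      w <- (1 / max(abs(dy), abs(dx)))^f
      r1 <- max(1, 1 - dy):min(nr, nr - dy)
      c1 <- max(1, 1 - dx):min(nc, nc - dx)
      if (length(r1) == 0 || length(c1) == 0) next
      a <- px[r1, c1, drop = FALSE]
      b <- px[r1 + dy, c1 + dx, drop = FALSE]
      vmin <- pmin(a, b); vmax <- pmax(a, b)
      # pair active for levels vmin .. vmax-1; difference-array update
      delta <- delta + 2 * w *
        (tabulate(vmin + 1, nbins = R) - tabulate(vmax + 1, nbins = R))
    }
  }
  vals <- cumsum(delta)
  vals[abs(vals) < 1e-9] <- 0  # kill FP dust so E(R-1) is exactly 0
  new("EnergyCurve", values = vals, d = d, f = f, levels = R)
}

#' Clip an energy curve
#'
#' The clipping threshold is `mean(curve) + median(curve)`; values above it
#' are replaced by the threshold. Clipping bounds the enhancement rate the
#' transfer function can apply at any one level. An all-zero curve (constant
#' image) is returned unchanged with threshold 0 and the degenerate flag
#' set.
#'
#' @param curve an [EnergyCurve].
#' @return a [ClippedCurve].
#' @export
clipEnergyCurve <- function(curve) {
  stopifnot(is(curve, "EnergyCurve"))
  v <- curve@values
  if (all(v == 0))
    return(new("ClippedCurve", values = v, clipThreshold = 0,
               degenerate = TRUE, levels = curve@levels))
  thr <- mean(v) + stats::median(v)
  new("ClippedCurve", values = pmin(v, thr), clipThreshold = thr,
      degenerate = FALSE, levels = curve@levels)
}

#' Partition the gray-level axis into three bands
#'
#' The energy-weighted spread `StD = sqrt(sum((l - m)^2 E(l)) / sum(E(l)))`
#' (with `m` the energy-weighted mean level) places the boundaries at
#' `loLow = round(lMin + StD)` and `loHigh = round(lMax - StD)`, where
#' `lMin`/`lMax` are the extreme levels present in the image. If the
#' boundaries cross or leave the open interval `(0, R-1)`, the fallback
#' takes energy-mass terciles of the clipped curve (the smallest levels at
#' which cumulative clipped energy crosses 1/3 and 2/3). A degenerate
#' (all-zero) curve falls back to terciles of a uniform pseudo-curve.
#'
#' @param clipped a [ClippedCurve].
#' @param img the source [GrayImage] (supplies `lMin`, `lMax`).
#' @return a [BandPartition].
#' @export
partitionBands <- function(clipped, img) {
  stopifnot(is(clipped, "ClippedCurve"), is(img, "GrayImage"))
  R <- clipped@levels
  px <- pixels(img)
  lMin <- min(px); lMax <- max(px)
  E <- clipped@values
  tot <- sum(E)
  lev <- 0:(R - 1)
  fallback <- FALSE
  stdW <- NA_real_
  if (clipped@degenerate || tot == 0) {
    E <- rep(1, R)  # uniform pseudo-curve
    tot <- R
    fallback <- TRUE
    stdW <- 0
    loLow <- loHigh <- NA_real_
  } else {
    m <- sum(lev * E) / tot
    stdW <- sqrt(sum((lev - m)^2 * E) / tot)
    loLow <- round(lMin + stdW)
    loHigh <- round(lMax - stdW)
    if (loLow >= loHigh || loLow <= 0 || loHigh >= R - 1) fallback <- TRUE
  }
  if (fallback) {
    cum <- cumsum(E) / tot
    loLow <- which(cum >= 1 / 3)[1] - 1
    loHigh <- which(cum >= 2 / 3)[1] - 1
    loLow <- min(max(loLow, 0), R - 2)
    loHigh <- min(max(loHigh, loLow + 1), R - 1)
  }
  new("BandPartition", loLow = loLow, loHigh = loHigh, stdW = stdW,
      lMin = lMin, lMax = lMax, levels = R, fallback = fallback)
}

# 1-based index ranges of the three bands on the level axis
.bandRanges <- function(bands) {
  R <- bands@levels
  list(lo = seq.int(1, bands@loLow + 1),
       me = seq.int(bands@loLow + 2, bands@loHigh + 1),
       up = if (bands@loHigh + 2 <= R) seq.int(bands@loHigh + 2, R)
            else integer(0))
}

#' Per-band probability densities and cumulative distributions
#'
#' Within each band the clipped energy is normalized by the band's total
#' energy to a pdf, and the cdf is the within-band cumulative sum. A band
#' whose clipped energy is zero gets a uniform pdf over its levels and is
#' flagged.
#'
#' @param clipped a [ClippedCurve].
#' @param bands a [BandPartition].
#' @return a list with elements `pdf`, `cdf` (each a list of vectors for
#'   bands `lo`, `me`, `up`) and `zeroMass` (named logical).
#' @export
bandDistributions <- function(clipped, bands) {
  stopifnot(is(clipped, "ClippedCurve"), is(bands, "BandPartition"))
  rng <- .bandRanges(bands)
  pdf <- list(); cdf <- list(); zero <- logical(0)
  for (nm in names(rng)) {
    idx <- rng[[nm]]
    if (length(idx) == 0) {
      pdf[[nm]] <- numeric(0); cdf[[nm]] <- numeric(0)
      zero[nm] <- FALSE
      next
    }
    e <- clipped@values[idx]
    p <- sum(e)
    if (p == 0) {
      pdf[[nm]] <- rep(1 / length(idx), length(idx))
      zero[nm] <- TRUE
    } else {
      pdf[[nm]] <- e / p
      zero[nm] <- FALSE
    }
    cdf[[nm]] <- cumsum(pdf[[nm]])
  }
  list(pdf = pdf, cdf = cdf, zeroMass = zero)
}

#' Build the piecewise transfer function
#'
#' Each band `[a, b]` is mapped onto its own output interval by
#' `TrF(l) = a + round((b - a) * cdf(l))`, so the three maps have disjoint
#' supports and their union is the full transfer function; outputs are
#' clamped to `[0, R-1]` and non-decreasing within each band.
#'
#' @param bands a [BandPartition].
#' @param dists the output of [bandDistributions()].
#' @return a [TransferFunction].
#' @export
buildTransferFunction <- function(bands, dists) {
  stopifnot(is(bands, "BandPartition"))
  R <- bands@levels
  rng <- .bandRanges(bands)
  mapping <- numeric(R)
  for (nm in names(rng)) {
    idx <- rng[[nm]]
    if (length(idx) == 0) next
    a <- idx[1] - 1; b <- idx[length(idx)] - 1
    mapping[idx] <- a + .roundHalfUp((b - a) * dists$cdf[[nm]])
  }
  mapping <- pmin(pmax(mapping, 0), R - 1)
  new("TransferFunction", mapping = mapping, levels = R)
}

#' Context-aware contrast enhancement
#'
#' End-to-end composition: energy curve, clipping, tri-band partition,
#' per-band pdf/cdf, piecewise transfer function, pixel remap. Entirely
#' deterministic. A constant image short-circuits unchanged (its energy
#' curve is identically zero) with the degenerate flag raised.
#'
#' @param img a [GrayImage].
#' @param d,f energy-curve parameters, see [computeEnergyCurve()].
#' @param report when `TRUE`, return the full processing record (curve,
#'   clipped curve, bands, transfer function, flags) alongside the image.
#' @return a [GrayImage] (or a report list).
#' @export
enhanceContrast <- function(img, d = 1, f = 1, report = FALSE) {
  stopifnot(is(img, "GrayImage"))
  curve <- computeEnergyCurve(img, d = d, f = f)
  if (all(curve@values == 0)) {
    flags <- list(degenerate = TRUE, fallback = FALSE,
                  zeroMass = c(lo = FALSE, me = FALSE, up = FALSE))
    if (!report) return(img)
    return(list(image = img, curve = curve, clipped = NULL, bands = NULL,
                trf = NULL, flags = flags))
  }
  clipped <- clipEnergyCurve(curve)
  bands <- partitionBands(clipped, img)
  dists <- bandDistributions(clipped, bands)
  trf <- buildTransferFunction(bands, dists)
  px <- pixels(img)
  out <- matrix(trf@mapping[px + 1], nrow(px), ncol(px))
  res <- GrayImage(out, levels = nLevels(img))
  flags <- list(degenerate = FALSE, fallback = bands@fallback,
                zeroMass = dists$zeroMass)
  if (!report) return(res)
  list(image = res, curve = curve, clipped = clipped, bands = bands,
      trf = trf, flags = flags)
}
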