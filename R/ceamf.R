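#' @useDynLib MammoPrep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# largest odd integer <= x, vectorized
.oddFloor <- function(x) {
  f <- floor(x)
  ifelse(f %% 2 == 0, f - 1, f)
}

#' Detect bright "light spot" artifacts
#'
#' Mammograms carry bright non-anatomical regions: view labels, lead
#' markers, opacity tags, machine-induced spots. These are found by
#' thresholding at `mean + kSigma * sd` of the pixel intensities and taking
#' 8-connected components of at least `minArea` pixels. Each spot records
#' its bounding-box height/width, its centroid (rounded to the nearest
#' pixel, 0-based row/column coordinates), and an effective radius
#' `min(he, wi) / 2`.
#'
#' @param img a [GrayImage].
#' @param kSigma threshold multiplier on the intensity standard deviation
#'   (default 2.5).
#' @param minArea minimum component area in pixels (default 16).
#' @return a `data.frame` with columns `cen_y`, `cen_x`, `he`, `wi`,
#'   `radius_a`, `area`, sorted by area descending; zero rows when nothing
#'   passes the threshold.
#' @export
detectLightSpots <- function(img, kSigma = 2.5, minArea = 16) {
  stopifnot(is(img, "GrayImage"))
  px <- pixels(img)
  thr <- mean(px) + kSigma * stats::sd(px)
  mask <- px > thr
  empty <- data.frame(cen_y = numeric(0), cen_x = numeric(0),
                      he = numeric(0), wi = numeric(0),
                      radius_a = numeric(0), area = numeric(0))
  if (!any(mask)) return(empty)
  lab <- .label8(mask)
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    if (nrow(w) < minArea) return(NULL)
    he <- diff(range(w[, 1])) + 1
    wi <- diff(range(w[, 2])) + 1
    data.frame(
      cen_y = floor(mean(w[, 1]) - 1 + 0.5),  # 0-based, round half up
      cen_x = floor(mean(w[, 2]) - 1 + 0.5),
      he = he, wi = wi, radius_a = min(he, wi) / 2, area = nrow(w))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) return(empty)
  rows <- rows[order(-rows$area), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Distance from a pixel to a light-spot center
#'
#' Plain Euclidean distance in pixel units; the per-pixel distance used by
#' the adaptive filter is the minimum over all detected spots.
#'
#' @param j,i 0-based pixel row and column.
#' @param spots one or more spot rows as returned by [detectLightSpots()].
#' @return the minimum Euclidean distance over the spots.
#' @export
spotDistance <- function(j, i, spots) {
  if (nrow(spots) == 0) return(Inf)
  min(sqrt((j - spots$cen_y)^2 + (i - spots$cen_x)^2))
}

#' Upper window cap from the detected spots
#'
#' The cap is a quarter of the smallest spot dimension (so the window never
#' outgrows the artifact it is meant to erase), floored to an odd integer
#' and never below the policy's lower bound. With no spots the configured
#' default cap applies.
#'
#' @param spots spot table from [detectLightSpots()].
#' @param policy a [WindowPolicy]; only `uMin` and `defaultCapNoSpots` are
#'   consulted.
#' @return an odd integer cap.
#' @export
windowCap <- function(spots, policy = WindowPolicy()) {
  stopifnot(is(policy, "WindowPolicy"))
  if (nrow(spots) == 0) return(policy@defaultCapNoSpots)
  u <- floor(min(pmin(spots$he, spots$wi)) / 4)
  u <- .oddFloor(u)
  max(u, policy@uMin)
}

# Per-pixel window-size map for a Z x M image. Inside a spot's effective
# radius the window grows exponentially toward the center (capped at sDis);
# outside it grows logarithmically with distance. Everything is floored to
# odd and clamped to [uMin, sDis].
.windowSizeMap <- function(nr, nc, spots, policy) {
  if (nrow(spots) == 0)
    return(matrix(as.integer(policy@uMin), nr, nc))
  dmin <- matrix(Inf, nr, nc)
  rad <- matrix(NA_real_, nr, nc)
  rowd <- 0:(nr - 1)
  cold <- 0:(nc - 1)
  for (k in seq_len(nrow(spots))) {
    dk <- sqrt(outer((rowd - spots$cen_y[k])^2, (cold - spots$cen_x[k])^2, "+"))
    upd <- dk < dmin
    rad[upd] <- spots$radius_a[k]
    dmin[upd] <- dk[upd]
  }
  uraw <- matrix(NA_real_, nr, nc)
  inside <- dmin < rad
  atCenter <- dmin == 0
  uraw[inside] <- 2 * (exp(rad[inside] / dmin[inside]) - 1) + 3
  uraw[!inside] <- 2 * log10(dmin[!inside] / rad[!inside]) + 3
  uraw[atCenter] <- policy@sDis  # exp branch diverges; the cap is its limit
  u <- .oddFloor(pmin(uraw, policy@sDis))
  u <- pmin(pmax(u, policy@uMin), policy@sDis)
  storage.mode(u) <- "integer"
  u
}

#' Adaptive window size at a pixel
#'
#' @param j,i 0-based pixel row and column.
#' @param spots spot table from [detectLightSpots()].
#' @param policy a [WindowPolicy] giving the odd bounds `[uMin, sDis]`.
#' @return an odd integer window side U. With no spots, `uMin`. Inside the
#'   nearest spot's effective radius, `2 (exp(a / s) - 1) + 3` with `a` the
#'   radius and `s` the distance (the cap when `s = 0`); outside,
#'   `2 log10(s / a) + 3`. The raw value is capped at `sDis`, floored to
#'   odd, and clamped to `[uMin, sDis]`.
#' @export
adaptiveWindowSize <- function(j, i, spots, policy = WindowPolicy()) {
  stopifnot(is(policy, "WindowPolicy"))
  if (nrow(spots) == 0) return(as.integer(policy@uMin))
  sdis <- spotDistance(j, i, spots)
  k <- which.min(sqrt((j - spots$cen_y)^2 + (i - spots$cen_x)^2))
  a <- spots$radius_a[k]
  uraw <- if (sdis == 0) policy@sDis
          else if (sdis < a) 2 * (exp(a / sdis) - 1) + 3
          else 2 * log10(sdis / a) + 3
  u <- .oddFloor(min(uraw, policy@sDis))
  as.integer(min(max(u, policy@uMin), policy@sDis))
}

#' Context/distance-adaptive median filter (CEAMF)
#'
#' Replaces every pixel with the median of an odd square window whose side
#' depends on the distance to the nearest detected bright artifact: windows
#' grow toward artifact centers so labels and opaque markers are smoothed
#' away, while tissue far from any artifact is filtered at the minimal 3x3.
#' Windows are clipped at the image border (no padding) and even-count
#' medians take the lower median, so every output value is attained in the
#' input window.
#'
#' @param img a [GrayImage].
#' @param spots spot table; detected from `img` with [detectLightSpots()]
#'   when `NULL`.
#' @param policy a [WindowPolicy]; when `NULL`, `uMin = 3` and
#'   `sDis = windowCap(spots)`.
#' @param kSigma,minArea passed to [detectLightSpots()] when spots are
#'   detected internally.
#' @param report when `TRUE`, return a list with the filtered image, the
#'   spot table and window-size summary statistics instead of the bare
#'   image.
#' @return a [GrayImage] (or a report list).
#' @examples
#' img <- GrayImage(matrix(100L, 32, 32))
#' out <- applyCEAMF(img)
#' identical(pixels(out), pixels(img))
#' @export
applyCEAMF <- function(img, spots = NULL, policy = NULL,
                       kSigma = 2.5, minArea = 16, report = FALSE) {
  stopifnot(is(img, "GrayImage"))
  if (is.null(spots)) spots <- detectLightSpots(img, kSigma, minArea)
  if (is.null(policy)) {
    base <- WindowPolicy()
    policy <- WindowPolicy(uMin = 3, sDis = windowCap(spots, base),
                           defaultCapNoSpots = base@defaultCapNoSpots)
  }
  stopifnot(is(policy, "WindowPolicy"))
  px <- pixels(img)
  u <- .windowSizeMap(nrow(px), ncol(px), spots, policy)
  pxi <- px
  storage.mode(pxi) <- "integer"
  out <- .ceamf_median(pxi, u)
  res <- GrayImage(out, levels = nLevels(img))
  if (!report) return(res)
  list(image = res, spots = spots, policy = policy,
       windowStats = list(min = min(u), max = max(u), mean = mean(u)))
}

#' Per-pixel window-size map
#'
#' Exposes the window-size field used by [applyCEAMF()] so the window law
#' (odd, within `[uMin, sDis]`) can be inspected directly.
#'
#' @inheritParams applyCEAMF
#' @return an integer matrix of odd window sides, same shape as the image.
#' @export
windowSizeMap <- function(img, spots = NULL, policy = NULL,
                          kSigma = 2.5, minArea = 16) {
  stopifnot(is(img, "GrayImage"))
  if (is.null(spots)) spots <- detectLightSpots(img, kSigma, minArea)
  if (is.null(policy)) {
    base <- WindowPolicy()
    policy <- WindowPolicy(uMin = 3, sDis = windowCap(spots, base),
                           defaultCapNoSpots = base@defaultCapNoSpots)
  }
  px <- pixels(img)
  .windowSizeMap(nrow(px), ncol(px), spots, policy)
}
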