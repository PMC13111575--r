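test_that("energy curve matches the 2x2 checkerboard worked example", {
  ec <- computeEnergyCurve(GrayImage(matrix(c(0L, 1L, 1L, 0L), 2, 2),
                                     levels = 2))
  expect_equal(ec@values, c(16, 0))
})

test_that("energy curve is zero exactly when the thresholded field is constant", {
  # constant image: all-zero curve
  expect_true(all(computeEnergyCurve(GrayImage(matrix(7L, 8, 8)))@values == 0))
  # all 2x2 binary images, by brute force
  for (code in 0:15) {
    px <- matrix(as.integer(intToBits(code)[1:4]), 2, 2)
    ec <- computeEnergyCurve(GrayImage(px, levels = 2))
    constant0 <- length(unique(as.vector(px))) == 1
    expect_equal(ec@values[1] == 0, constant0)
    expect_equal(ec@values[2], 0)  # no pixel exceeds the top level
  }
})

test_that("energy curve agrees with the naive definition on fuzzed images", {
  for (s in 1:4) {
    img <- randomGrayImage(7, 9, R = 16, seed = s)
    expect_equal(computeEnergyCurve(img)@values,
                 naiveEnergyCurve(pixels(img), 16), tolerance = 1e-9)
  }
  # d = 2 with inverse-distance weighting f = 2
  img <- randomGrayImage(6, 6, R = 8, seed = 10)
  expect_equal(computeEnergyCurve(img, d = 2, f = 2)@values,
               naiveEnergyCurve(pixels(img), 8, d = 2, f = 2),
               tolerance = 1e-9)
})

test_that("energy curve is invariant under transposition and 90-degree rotation", {
  img <- randomGrayImage(11, 11, R = 32, seed = 2)
  base <- computeEnergyCurve(img)@values
  tr <- GrayImage(t(pixels(img)), levels = 32)
  rot <- GrayImage(t(pixels(img)[nrow(pixels(img)):1, ]), levels = 32)
  expect_equal(computeEnergyCurve(tr)@values, base)
  expect_equal(computeEnergyCurve(rot)@values, base)
})

test_that("clipping uses mean + median and bounds the curve", {
  curve <- new("EnergyCurve", values = c(10, 30, 2, 0), d = 1, f = 1,
               levels = 4)
  cl <- clipEnergyCurve(curve)
  expect_equal(cl@clipThreshold, mean(c(10, 30, 2, 0)) + 6)  # median 6
  expect_equal(cl@values, pmin(c(10, 30, 2, 0), cl@clipThreshold))

  # spec-style 3-level example: [10, 30, 2] -> threshold 24 -> [10, 24, 2]
  c3 <- new("EnergyCurve", values = c(10, 30, 2, 0), d = 1, f = 1, levels = 4)
  # curve below its threshold is unchanged
  low <- new("EnergyCurve", values = c(1, 2, 1, 0), d = 1, f = 1, levels = 4)
  expect_equal(clipEnergyCurve(low)@values, c(1, 2, 1, 0))
  # degenerate all-zero curve: unchanged, threshold 0, flagged
  z <- new("EnergyCurve", values = rep(0, 4), d = 1, f = 1, levels = 4)
  expect_true(clipEnergyCurve(z)@degenerate)
  expect_equal(clipEnergyCurve(z)@clipThreshold, 0)
})

test_that("clip threshold mean + median matches direct arithmetic on 3 levels", {
  # [10, 30, 2]: mean 14, median 10, threshold 24 -> [10, 24, 2]
  vals <- c(10, 30, 2)
  thr <- mean(vals) + median(vals)
  expect_equal(thr, 24)
  expect_equal(pmin(vals, thr), c(10, 24, 2))
})

test_that("band partition follows the weighted-spread rule with tercile fallback", {
  R <- 256
  # energy concentrated at a single level: StD = 0 -> boundaries at lMin/lMax
  px <- matrix(c(rep(64L, 50), rep(192L, 50)), 10, 10)
  E <- rep(0, R); E[101] <- 5  # all clipped energy at level 100
  cl <- new("ClippedCurve", values = E, clipThreshold = 5,
            degenerate = FALSE, levels = R)
  bp <- partitionBands(cl, GrayImage(px))
  expect_equal(bp@stdW, 0)
  expect_equal(bp@loLow, 64)   # lMin + 0
  expect_equal(bp@loHigh, 192) # lMax - 0
  expect_false(bp@fallback)

  # symmetric two-spike curve: m = 128, StD = 64, boundaries collide ->
  # tercile fallback
  E2 <- rep(0, R); E2[65] <- 3; E2[193] <- 3
  cl2 <- new("ClippedCurve", values = E2, clipThreshold = 10,
             degenerate = FALSE, levels = R)
  bp2 <- partitionBands(cl2, GrayImage(px))
  expect_true(bp2@fallback)
  expect_true(bp2@loLow < bp2@loHigh)
  expect_equal(bp2@loLow, 64)   # first level where cum energy >= 1/3
  expect_equal(bp2@loHigh, 192) # first level where cum energy >= 2/3

  # bands always partition [0, R-1]
  for (s in 1:5) {
    img <- randomGrayImage(16, 16, seed = 30 + s)
    cl3 <- clipEnergyCurve(computeEnergyCurve(img))
    b <- partitionBands(cl3, img)
    expect_true(b@loLow >= 0 && b@loLow < b@loHigh && b@loHigh <= R - 1)
  }
})

test_that("band pdfs sum to 1 and cdfs end at 1; uniform energy gives a linear cdf", {
  img <- randomGrayImage(16, 16, seed = 3)
  cl <- clipEnergyCurve(computeEnergyCurve(img))
  bands <- partitionBands(cl, img)
  dists <- bandDistributions(cl, bands)
  for (nm in c("lo", "me", "up")) {
    if (length(dists$pdf[[nm]]) == 0) next
    expect_equal(sum(dists$pdf[[nm]]), 1, tolerance = 1e-9)
    expect_equal(dists$cdf[[nm]][length(dists$cdf[[nm]])], 1,
                 tolerance = 1e-9)
  }
  # uniform clipped energy over a band of width w -> cdf(k) = k/w
  R <- 30
  E <- rep(1, R)
  cl2 <- new("ClippedCurve", values = E, clipThreshold = 2,
             degenerate = FALSE, levels = R)
  b2 <- new("BandPartition", loLow = 9, loHigh = 19, stdW = 1,
            lMin = 0, lMax = R - 1, levels = R, fallback = FALSE)
  d2 <- bandDistributions(cl2, b2)
  expect_equal(d2$cdf$lo, (1:10) / 10)
})

test_that("transfer function maps each band onto its own interval", {
  R <- 30
  b <- new("BandPartition", loLow = 9, loHigh = 19, stdW = 1,
           lMin = 0, lMax = R - 1, levels = R, fallback = FALSE)
  # uniform energy in band [0, 9] -> TrF(l) = round(9 (l+1) / 10)
  E <- rep(1, R)
  cl <- new("ClippedCurve", values = E, clipThreshold = 2,
            degenerate = FALSE, levels = R)
  trf <- buildTransferFunction(b, bandDistributions(cl, b))
  expect_equal(trf@mapping[1:10], floor(9 * (1:10) / 10 + 0.5))

  # cdf saturated at 1 (all band mass at the first level) -> everything maps
  # to the band top
  E2 <- rep(0, R); E2[c(1, 11, 21)] <- 1
  cl2 <- new("ClippedCurve", values = E2, clipThreshold = 1,
             degenerate = FALSE, levels = R)
  trf2 <- buildTransferFunction(b, bandDistributions(cl2, b))
  expect_true(all(trf2@mapping[1:10] == 9))
  expect_true(all(trf2@mapping[11:20] == 19))
  expect_true(all(trf2@mapping[21:30] == 29))
})

test_that("transfer function is monotone within bands and in range on fuzzed inputs", {
  for (s in 1:10) {
    img <- randomGrayImage(12, 12, seed = 40 + s)
    rep_ <- enhanceContrast(img, report = TRUE)
    trf <- rep_$trf
    b <- rep_$bands
    expect_gte(min(trf@mapping), 0)
    expect_lte(max(trf@mapping), 255)
    idx <- list(1:(b@loLow + 1), (b@loLow + 2):(b@loHigh + 1),
                if (b@loHigh + 2 <= 256) (b@loHigh + 2):256 else integer(0))
    for (ii in idx)
      if (length(ii) > 1) expect_true(all(diff(trf@mapping[ii]) >= 0))
  }
})

test_that("contrast enhancement short-circuits constant images and is deterministic", {
  cst <- GrayImage(matrix(123L, 16, 16))
  out <- enhanceContrast(cst, report = TRUE)
  expect_true(out$flags$degenerate)
  expect_identical(pixels(out$image), pixels(cst))

  img <- randomGrayImage(24, 24, seed = 9)
  expect_identical(pixels(enhanceContrast(img)), pixels(enhanceContrast(img)))
})

test_that("enhancement widens the range of a low-contrast phantom", {
  set.seed(77)
  px <- matrix(sample(100:156, 64 * 64, TRUE), 64, 64)
  img <- GrayImage(px)
  out <- enhanceContrast(img)
  expect_gt(diff(range(pixels(out))), diff(range(px)))
})

test_that("ranks are preserved within each band", {
  img <- randomGrayImage(16, 16, seed = 55)
  rep_ <- enhanceContrast(img, report = TRUE)
  m <- rep_$trf@mapping
  b <- rep_$bands
  bandOf <- function(l) ifelse(l <= b@loLow, 1, ifelse(l <= b@loHigh, 2, 3))
  px <- as.vector(pixels(img))
  for (k in 1:200) {
    set.seed(k)
    pq <- sample(px, 2)
    if (bandOf(pq[1]) == bandOf(pq[2]) && pq[1] <= pq[2])
      expect_lte(m[pq[1] + 1], m[pq[2] + 1])
  }
})
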