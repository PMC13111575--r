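test_that("light-spot detection matches brute-force component labeling", {
  # constant image: nothing above threshold
  expect_equal(nrow(detectLightSpots(GrayImage(matrix(50L, 32, 32)))), 0)

  # one 20x10 bright rectangle on a zero background
  px <- matrix(0L, 64, 64)
  px[11:30, 21:30] <- 255L
  spots <- detectLightSpots(GrayImage(px))
  expect_equal(nrow(spots), 1)
  expect_equal(spots$he, 20)
  expect_equal(spots$wi, 10)
  # centroid: rows 11..30 -> mean 20.5 (1-based) -> 0-based 19.5 -> 20 half-up
  expect_equal(spots$cen_y, 20)
  expect_equal(spots$cen_x, 25)
  expect_equal(spots$radius_a, 5)

  # two disjoint blobs, both above min area
  px2 <- matrix(0L, 48, 48)
  px2[2:7, 2:7] <- 255L
  px2[30:40, 30:38] <- 255L
  spots2 <- detectLightSpots(GrayImage(px2))
  expect_equal(nrow(spots2), 2)
  expect_equal(spots2$area[1], 11 * 9)  # sorted by area descending
  expect_equal(spots2$area[2], 36)
})

test_that("8-connected labeling agrees with a naive flood fill on fuzzed masks", {
  for (s in 1:5) {
    set.seed(s)
    mask <- matrix(runif(30 * 25) < 0.35, 30, 25)
    a <- MammoPrep:::.label8(mask)
    b <- naiveLabel8(mask)
    expect_equal(max(a), max(b))
    # same partition: component memberships coincide
    key <- function(l) vapply(split(seq_along(l), l), paste, "", collapse = ",")
    expect_setequal(unname(key(as.vector(a))[-1]),
                    unname(key(as.vector(b))[-1]))
  }
})

test_that("spot distance is Euclidean and the minimum over spots", {
  sp <- data.frame(cen_y = c(10, 40), cen_x = c(10, 40),
                   he = c(8, 8), wi = c(8, 8), radius_a = 4, area = 64)
  expect_equal(spotDistance(10, 10, sp), 0)
  expect_equal(spotDistance(13, 14, sp), 5)  # 3-4-5 triangle
  set.seed(3)
  for (k in 1:20) {
    j <- sample(0:60, 1); i <- sample(0:60, 1)
    expect_equal(spotDistance(j, i, sp),
                 min(sqrt((j - sp$cen_y)^2 + (i - sp$cen_x)^2)))
  }
})

test_that("window cap follows the quarter-minimum-dimension rule", {
  pol <- WindowPolicy()
  expect_equal(windowCap(data.frame(he = 20, wi = 25), pol), 5)
  expect_equal(windowCap(data.frame(he = 8, wi = 12), pol), 3)   # raised to 3
  expect_equal(windowCap(data.frame(he = c(40, 28), wi = c(36, 30)), pol), 7)
  empty <- data.frame(he = numeric(0), wi = numeric(0))
  expect_equal(windowCap(empty, pol), 9)
})

test_that("adaptive window size follows the exp/log branches and limits", {
  none <- data.frame(cen_y = numeric(0), cen_x = numeric(0), he = numeric(0),
                     wi = numeric(0), radius_a = numeric(0), area = numeric(0))
  expect_equal(adaptiveWindowSize(5, 5, none, WindowPolicy()), 3L)

  sp <- data.frame(cen_y = 0, cen_x = 0, he = 2, wi = 2, radius_a = 1, area = 4)
  # at the spot center the exp branch diverges; the cap is its limit
  expect_equal(adaptiveWindowSize(0, 0, sp, WindowPolicy(sDis = 31)), 31L)
  # log branch: sdis = 100, a = 1 -> 2*log10(100) + 3 = 7
  expect_equal(adaptiveWindowSize(0, 100, sp, WindowPolicy(sDis = 31)), 7L)
  # exp branch: sdis = 1, a = 2 -> 2(e^2 - 1) + 3 ~ 15.78, capped at 9
  sp2 <- data.frame(cen_y = 0, cen_x = 0, he = 4, wi = 4, radius_a = 2, area = 16)
  expect_equal(adaptiveWindowSize(0, 1, sp2, WindowPolicy(sDis = 9)), 9L)
})

test_that("window-size map is odd and within [uMin, sDis] everywhere", {
  for (s in 1:5) {
    pc <- generatePhantomCase(phantomConfig(side = 64, seed = s))
    u <- windowSizeMap(pc$image)
    spots <- detectLightSpots(pc$image)
    cap <- windowCap(spots, WindowPolicy())
    expect_true(all(u %% 2 == 1))
    expect_true(all(u >= 3 & u <= cap))
  }
})

test_that("CEAMF equals a brute-force per-pixel median with the same window map", {
  for (s in 1:4) {
    img <- randomGrayImage(32, 32, seed = s)
    spots <- detectLightSpots(img)
    u <- windowSizeMap(img, spots = spots)
    out <- applyCEAMF(img, spots = spots)
    expect_identical(pixels(out), naiveMedianFilter(pixels(img), u))
  }
  # non-square, with a planted bright spot forcing varying windows
  set.seed(99)
  px <- matrix(sample(30:60, 64 * 48, TRUE), 64, 48)
  px[5:24, 5:24] <- 255L
  img <- GrayImage(px)
  spots <- detectLightSpots(img, kSigma = 2)
  expect_gt(nrow(spots), 0)
  u <- windowSizeMap(img, spots = spots)
  expect_gt(max(u), min(u))  # windows actually vary near the spot
  expect_identical(pixels(applyCEAMF(img, spots = spots)),
                   naiveMedianFilter(pixels(img), u))
})

test_that("CEAMF removes a single impulse and never invents intensities", {
  px <- matrix(40L, 21, 21)
  px[11, 11] <- 255L
  out <- applyCEAMF(GrayImage(px),
                    spots = data.frame(cen_y = numeric(0), cen_x = numeric(0),
                                       he = numeric(0), wi = numeric(0),
                                       radius_a = numeric(0), area = numeric(0)))
  expect_true(all(pixels(out) == 40L))

  for (s in 1:3) {
    img <- randomGrayImage(24, 24, seed = 10 + s)
    out <- applyCEAMF(img)
    expect_true(all(pixels(out) %in% pixels(img)))   # attained values only
    expect_gte(min(pixels(out)), min(pixels(img)))   # non-expansive range
    expect_lte(max(pixels(out)), max(pixels(img)))
  }
})

test_that("CEAMF strictly reduces MAE on salt-and-pepper-corrupted phantoms", {
  for (s in 1:5) {
    pc <- generatePhantomCase(phantomConfig(
      side = 96, seed = s,
      noise = list(kind = "salt_pepper", params = list(rate = 0.10))))
    clean <- pixels(pc$clean)
    before <- mean(abs(pixels(pc$image) - clean))
    after <- mean(abs(pixels(applyCEAMF(pc$image)) - clean))
    expect_lt(after, before)
  }
})
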