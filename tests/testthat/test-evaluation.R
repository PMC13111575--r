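test_that("classification metrics match the worked confusion example", {
  m <- classificationMetrics(TP = 9, TN = 8, FP = 1, FN = 2)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["sensitivity"]), 9 / 11, tolerance = 1e-12)
  expect_equal(unname(m["specificity"]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(m["precision"]), 0.9)
  expect_equal(unname(m["f1"]), 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11),
               tolerance = 1e-12)
  expect_length(attr(m, "undefined"), 0)
})

test_that("perfect classifiers score 1 and empty denominators are flagged NA", {
  m <- classificationMetrics(TP = 5, TN = 7, FP = 0, FN = 0)
  expect_true(all(m == 1))

  m2 <- classificationMetrics(TP = 0, TN = 3, FP = 0, FN = 4)
  expect_equal(unname(m2["sensitivity"]), 0)
  expect_true(is.na(m2["precision"]))
  expect_true(is.na(m2["f1"]))
  expect_setequal(attr(m2, "undefined"), c("precision", "f1"))

  expect_error(classificationMetrics(0, 0, 0, 0), "zero")
})

test_that("ratio metrics stay in [0,1] over fuzzed counts", {
  set.seed(1)
  for (k in 1:50) {
    cc <- as.list(sample(0:30, 4, replace = TRUE))
    if (sum(unlist(cc)) == 0) next
    m <- do.call(classificationMetrics, cc)
    ok <- !is.na(m)
    expect_true(all(m[ok] >= 0 & m[ok] <= 1))
  }
})

test_that("dice and iou follow their definitions and identity", {
  P <- matrix(0L, 8, 8); G <- matrix(0L, 8, 8)
  P[1:2, 1:2] <- 1L; G[1:2, 1:2] <- 1L
  expect_equal(diceCoefficient(P, G), 1)
  expect_equal(iouScore(P, G), 1)

  G2 <- matrix(0L, 8, 8); G2[5:6, 5:6] <- 1L
  expect_equal(diceCoefficient(P, G2), 0)
  expect_equal(iouScore(P, G2), 0)

  # |P| = 4, |G| = 4, |intersection| = 2
  P3 <- matrix(0L, 4, 4); P3[1, 1:4] <- 1L
  G3 <- matrix(0L, 4, 4); G3[1, 3:4] <- 1L; G3[2, 1:2] <- 1L
  expect_equal(diceCoefficient(P3, G3), 0.5)
  expect_equal(iouScore(P3, G3), 1 / 3, tolerance = 1e-12)

  expect_error(diceCoefficient(P, matrix(0L, 4, 4)), "shape")

  # both empty: perfect agreement on absence, flagged
  E <- matrix(0L, 5, 5)
  expect_equal(as.numeric(diceCoefficient(E, E)), 1)
  expect_true(attr(diceCoefficient(E, E), "bothEmpty"))

  # dice = 2 iou / (1 + iou) on fuzzed pairs; dice >= iou
  for (s in 1:20) {
    set.seed(s)
    P <- matrix(as.integer(runif(64) < 0.4), 8, 8)
    G <- matrix(as.integer(runif(64) < 0.4), 8, 8)
    d <- as.numeric(diceCoefficient(P, G))
    i <- as.numeric(iouScore(P, G))
    expect_equal(d, 2 * i / (1 + i), tolerance = 1e-12)
    expect_gte(d, i)
    if (!d %in% c(0, 1)) expect_gt(d, i)
  }
})

test_that("case-level aggregation is the unweighted view mean", {
  df <- data.frame(case_id = c("a", "b", "b", "c"),
                   view = c("CC", "CC", "MLO", "CC"),
                   score = c(0.6, 0.8, 0.9, 1.0))
  agg <- aggregateCaseLevel(df)
  expect_equal(agg$score[agg$case_id == "b"], 0.85)
  expect_equal(agg$score[agg$case_id == "a"], 0.6)
  expect_equal(nrow(agg), 3)

  # equals an independent group-by mean on fuzzed inputs
  set.seed(2)
  df2 <- data.frame(case_id = sample(letters[1:8], 60, TRUE),
                    score = runif(60))
  agg2 <- aggregateCaseLevel(df2)
  ref <- sapply(split(df2$score, df2$case_id), mean)
  expect_equal(agg2$score, unname(ref[agg2$case_id]))
})

test_that("bootstrap CI degenerates to a point on constant scores", {
  s <- bootstrapCI(rep(0.7, 10), seed = 1)
  expect_equal(s$ciLow, 0.7)
  expect_equal(s$ciHigh, 0.7)
  expect_equal(s$sd, 0)
})

test_that("bootstrap replays the seeded resampling exactly", {
  scores <- c(0, 1)
  s <- bootstrapCI(scores, nResamples = 4, seed = 7)
  # independent replay of the same generator sequence
  set.seed(7)
  idx <- matrix(sample.int(2, 8, replace = TRUE), nrow = 4)
  means <- rowMeans(matrix(scores[idx], nrow = 4))
  expect_equal(s$ciLow, unname(quantile(means, 0.025)))
  expect_equal(s$ciHigh, unname(quantile(means, 0.975)))
})

test_that("bootstrap CI bounds are ordered and within the score range", {
  for (s in 1:10) {
    set.seed(s)
    x <- runif(sample(3:30, 1))
    ci <- bootstrapCI(x, nResamples = 200, seed = s)
    expect_lte(ci$ciLow, ci$ciHigh)
    expect_gte(ci$ciLow, min(x))
    expect_lte(ci$ciHigh, max(x))
  }
  expect_error(bootstrapCI(0.5), "at least 2")
})

test_that("bootstrap CI width shrinks with the case count", {
  widths <- sapply(c(20, 200), function(n) {
    median(sapply(1:50, function(s) {
      set.seed(s)
      ci <- bootstrapCI(rnorm(n, 0.8, 0.1), nResamples = 200, seed = s)
      ci$ciHigh - ci$ciLow
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("paired t-test matches the closed form and handles degeneracies", {
  # d = {1, 2, 3}: t = 2 / (1/sqrt(3)) = 2 sqrt(3)
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  r <- pairedTTest(a, b)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)

  # identical series: nothing to test
  same <- pairedTTest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # constant nonzero differences: undefined statistic
  expect_error(pairedTTest(a, a + 2), "constant")

  # closed form on fuzzed small integer examples
  for (s in 1:10) {
    set.seed(s)
    n <- sample(3:10, 1)
    x <- sample(0:20, n, TRUE); y <- sample(0:20, n, TRUE)
    d <- x - y
    if (sd(d) == 0) next
    r <- pairedTTest(x, y)
    tExp <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(r$t, tExp, tolerance = 1e-9)
    expect_equal(r$p, 2 * pt(-abs(tExp), n - 1), tolerance = 1e-9)
  }
})

test_that("threshold sweep produces valid operating points", {
  set.seed(3)
  truth <- rbinom(50, 1, 0.4)
  prob <- pmin(pmax(truth * 0.6 + runif(50, 0, 0.4), 0), 1)
  sw <- thresholdSweep(prob, truth)
  expect_true(all(sw$tpr >= 0 & sw$tpr <= 1, na.rm = TRUE))
  expect_true(all(diff(sw$tpr) <= 1e-12))  # tpr non-increasing in threshold
  cc <- confusionCounts(prob, truth, 0.5)
  expect_equal(sum(cc), 50)
})
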