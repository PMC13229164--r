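test_that("repeatability CV uses the sample SD and is scale invariant", {
  p <- cvPrecision(c(1, 2, 3))
  expect_equal(p@mean, 2)
  expect_equal(p@sd, 1)
  expect_equal(p@cv, 50)

  expect_equal(cvPrecision(rep(0.02, 4))@cv, 0)

  set.seed(41)
  x <- runif(8, 0.01, 0.05)
  for (k in c(0.1, 3, 1000))
    expect_equal(cvPrecision(k * x)@cv, cvPrecision(x)@cv,
                 tolerance = 1e-12)

  expect_error(cvPrecision(0.02), "at least 2")
  expect_error(cvPrecision(c(-1, 1)), "> 0")
})

test_that("z-score, bias and En number arithmetic and antisymmetry", {
  expect_equal(zScore(0.5, 0.4, 0.05), 2)
  expect_equal(zScore(0.4, 0.4, 0.05), 0)
  expect_equal(zScore(0.4, 0.5, 0.05), -zScore(0.5, 0.4, 0.05))
  expect_error(zScore(0.5, 0.4, 0), "> 0")

  expect_equal(biasPercent(0.5, 0.5), 0)
  # antisymmetric up to the exchanged denominator
  expect_equal(biasPercent(0.7, 0.5) * 0.5, -biasPercent(0.5, 0.7) * 0.7)
  expect_error(biasPercent(0.5, 0), "> 0")

  expect_equal(enNumber(0.5, 0.5, 0.1, 0.1), 0)
  expect_equal(enNumber(0.7, 0.5, 0.1, 0.02),
               -enNumber(0.5, 0.7, 0.02, 0.1))
  expect_error(enNumber(0.5, 0.4, 0, 0), "zero")
})

test_that("performance verdicts use strict magnitude criteria", {
  ok <- evaluatePerformance(list(z = -0.1, deltaX = -3.1, en = -0.1))
  expect_true(all(ok))

  expect_false(evaluatePerformance(list(z = 2, deltaX = 0, en = 0))["z"])
  expect_true(evaluatePerformance(list(z = -1.99, deltaX = 0, en = 0))["z"])
  expect_false(evaluatePerformance(list(z = 0, deltaX = -30, en = 0))["bias"])
  expect_false(evaluatePerformance(list(z = 0, deltaX = -25, en = 0))["bias"])
  expect_true(evaluatePerformance(list(z = 0, deltaX = 49.9, en = 0))["bias"])
  expect_false(evaluatePerformance(list(z = 0, deltaX = 50, en = 0))["bias"])
  expect_false(evaluatePerformance(list(z = 0, deltaX = 0, en = 1))["en"])
  expect_true(is.na(evaluatePerformance(
    intercomparisonScore(0.5, 0.4, 0.1, 0.05))["z"]))
})

test_that("report rounding: one decimal below 10 %, whole percent above", {
  expect_equal(roundBias(-3.0612), -3.1)
  expect_equal(roundBias(10.9063), 11)
  expect_equal(roundBias(c(9.94, -12.3)), c(9.9, -12))
  expect_equal(roundScore(0.6134), 0.6)
  expect_equal(roundConcentration(0.0119239), 0.0119)
})

test_that("stability chart flags only genuine excursions", {
  h <- data.frame(date = as.Date("2023-01-01") + 90 * (0:7),
                  detectorId = "D1",
                  peakArea = c(1000, 1010, 995, 1005, 998, 1002, 1007, 996),
                  centroid = c(5150.1, 5150.3, 5149.8, 5150.0, 5150.2,
                               5149.9, 5150.1, 5150.0),
                  fwhm = c(18.2, 18.5, 18.1, 18.4, 18.3, 18.2, 18.4, 18.3))
  out <- stabilityChart(h)
  expect_false(any(out$flagArea | out$flagCentroid | out$flagFwhm))

  # shift the last centroid by ~10 baseline SDs
  h2 <- h
  h2$centroid[8] <- h2$centroid[8] + 10 * sd(h$centroid[1:7])
  out2 <- stabilityChart(h2)
  expect_true(out2$flagCentroid[8])
  expect_false(any(out2$flagCentroid[1:7]))
  expect_false(any(out2$flagArea))

  expect_error(stabilityChart(h[1, ]), "at least 2")
  expect_error(stabilityChart(h[, -3]), "columns")

  lim <- attr(out, "limits")$D1$centroid
  expect_lt(lim["lower"], min(h$centroid[1:7]))
  expect_gt(lim["upper"], max(h$centroid[1:7]))
})
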