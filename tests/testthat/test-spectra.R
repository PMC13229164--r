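test_that("SPE dialect parses counts, live time and calibration and round-trips", {
  f <- tempfile(fileext = ".spe")
  writeLines(c("$SPEC_ID:", "D7", "$MEAS_TIM:", "345600 345800",
               "$DATA:", "0 3", "1", "2", "3", "4"), f)
  sp <- readSpectrum(f, "spe")
  expect_s4_class(sp, "AlphaSpectrum")
  expect_identical(counts(sp), c(1L, 2L, 3L, 4L))
  expect_equal(liveTime(sp), 345600)
  expect_identical(detectorId(sp), "D7")
  expect_null(calibration(sp))

  # full round trip incl. energy fit
  sp2 <- alphaSpectrum(c(0, 12, 345, 6), liveTime = 518400,
                       detectorId = "PIPS-1",
                       calibration = energyCalibration(6.25, 12.5))
  f2 <- tempfile(fileext = ".spe")
  writeSpectrum(sp2, f2)
  back <- readSpectrum(f2, "spe")
  expect_identical(counts(back), counts(sp2))
  expect_identical(liveTime(back), liveTime(sp2))
  expect_equal(calibration(back)@slope, 6.25)
  expect_equal(calibration(back)@intercept, 12.5)
})

test_that("malformed SPE input raises parse errors naming the problem", {
  f <- tempfile()
  writeLines(c("$MEAS_TIM:", "600 600", "$DATA:"), f)
  expect_error(readSpectrum(f, "spe"), "DATA")
  writeLines(c("$MEAS_TIM:", "600 600", "$DATA:", "0 2", "1", "2.5", "3"), f)
  expect_error(readSpectrum(f, "spe"), "integer")
  writeLines(c("$DATA:", "0 1", "1", "2"), f)
  expect_error(readSpectrum(f, "spe"), "MEAS_TIM")
  writeLines(c("$MEAS_TIM:", "600 600", "$DATA:", "0 4", "1", "2"), f)
  expect_error(readSpectrum(f, "spe"), "declares")
})

test_that("two-column dialect parses header live time and round-trips", {
  f <- tempfile(fileext = ".txt")
  sp <- alphaSpectrum(c(5, 0, 7, 1), liveTime = 7200, detectorId = "D2")
  writeSpectrum(sp, f, "two_column")
  back <- readSpectrum(f, "two_column")
  expect_identical(counts(back), counts(sp))
  expect_equal(liveTime(back), 7200)
  expect_identical(detectorId(back), "D2")

  writeLines(c("0\t5", "1\t3"), f)  # no live time header
  expect_error(readSpectrum(f, "two_column"), "live_time_s")
})

test_that("energy calibration matches the exact line and a normal-equations oracle", {
  cal <- calibrateEnergy(c(100, 200), c(4000, 5000))
  expect_equal(cal@slope, 10)
  expect_equal(cal@intercept, 3000)

  # collinear points: zero residuals
  cal3 <- calibrateEnergy(c(10, 20, 30), c(100, 200, 300))
  expect_lt(max(abs(cal3@residuals)), 1e-9)

  # noisy four-line fit vs closed-form least squares
  set.seed(11)
  ch <- c(120, 380, 610, 905)
  en <- 1000 + 5.5 * ch + rnorm(4, 0, 3)
  X <- cbind(1, ch)
  beta <- drop(solve(t(X) %*% X, t(X) %*% en))
  cal4 <- calibrateEnergy(ch, en)
  expect_equal(cal4@intercept, unname(beta[1]), tolerance = 1e-9)
  expect_equal(cal4@slope, unname(beta[2]), tolerance = 1e-9)

  expect_error(calibrateEnergy(c(5, 5), c(100, 200)), "distinct")
  expect_error(calibrateEnergy(100, 4000), "distinct")
})

test_that("ROI integration: symmetric peak, empty window, analytic FWHM", {
  sp <- alphaSpectrum(c(0, 5, 10, 5, 0), 3600,
                      calibration = energyCalibration(10, 0))
  pk <- integrateROI(sp, roi("demo", 5, 45))
  expect_equal(pk@grossCounts, 20)
  expect_equal(pk@centroid, 20)  # middle channel energy

  empty <- integrateROI(sp, roi("bg", 35, 45))
  expect_equal(empty@grossCounts, 0)
  expect_true(is.na(empty@fwhm))
  expect_true(is.na(empty@centroid))

  # Gaussian sigma = 10 keV: FWHM = 2 sqrt(2 ln 2) * 10 = 23.55 keV
  g <- gaussSpectrum(area = 1e6, e0 = 1000, sigmaKeV = 10)
  pk <- integrateROI(g, roi("analyte", 900, 1100))
  expect_equal(pk@fwhm, 2 * sqrt(2 * log(2)) * 10, tolerance = 1 / 23.55)
  expect_equal(pk@centroid, 1000, tolerance = 1e-3)

  expect_error(integrateROI(alphaSpectrum(c(1, 2), 60), roi("x", 0, 1)),
               "calibrated")
  expect_error(integrateROI(sp, roi("x", 500, 600)), "outside")
})

test_that("ROI integration is additive under any interior split", {
  set.seed(21)
  for (rep in 1:10) {
    sp <- alphaSpectrum(rpois(200, 5), 1000,
                        calibration = energyCalibration(4, 100))
    lo <- runif(1, 100, 500); hi <- runif(1, lo + 50, 850)
    cut <- runif(1, lo, hi)
    whole <- integrateROI(sp, roi("w", lo, hi))@grossCounts
    left <- integrateROI(sp, roi("l", lo, cut))@grossCounts
    right <- integrateROI(sp, roi("r", cut, hi))@grossCounts
    expect_identical(left + right, whole)
  }
})

test_that("counting efficiency is counts per emitted alpha, with plausibility warnings", {
  expect_equal(countingEfficiency(8640, 86400, 0.4), 0.25)
  expect_equal(countingEfficiency(100 * 0.3, 100, 0.3), 1) |>
    expect_warning("0.5")
  expect_warning(e0 <- countingEfficiency(0, 86400, 0.4), "zero")
  expect_equal(e0, 0)
  expect_error(countingEfficiency(100, 0, 0.4), "> 0")
  expect_error(countingEfficiency(100, 86400, -1), "> 0")
})

test_that("default ROIs are disjoint windows around the polonium lines", {
  rois <- defaultROIs()
  expect_equal(rois$tracer@eLow, 4883 - 60)
  expect_equal(rois$analyte@eHigh, 5304.3 + 40)
  expect_lt(rois$tracer@eHigh, rois$analyte@eLow)
  expect_error(defaultROIs(lowOffset = 300, highOffset = 300), "overlap")
})
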