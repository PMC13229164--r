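test_that("daily excreted activity is concentration times 24-h volume", {
  expect_equal(dailyExcretion(0.02, 1.5), 0.03)
  expect_equal(dailyExcretion(0, 2), 0)
  expect_equal(dailyExcretion(0.02, 3), 2 * dailyExcretion(0.02, 1.5))
  expect_error(dailyExcretion(0.02, 0), "> 0")
  expect_error(dailyExcretion(0.02, -1), "> 0")
})

test_that("median normalization: conventions, self-identity and scale invariance", {
  out <- normalizeToMedian(c(1, 2, 3), 3)
  expect_equal(out$median, 2)
  expect_equal(out$ratios, 1.5)

  # even group size: mean of the middle two
  expect_equal(normalizeToMedian(c(1, 2, 4, 10), 3)$median, 3)
  expect_equal(normalizeToMedian(c(1, 2, 4, 10), 3)$ratios, 1)

  set.seed(51)
  for (n in c(7, 12)) {
    g <- rlnorm(n, -3, 1)
    self <- normalizeToMedian(g)
    expect_equal(median(self$ratios), 1)
    expect_equal(normalizeToMedian(17 * g, 17 * g)$ratios, self$ratios,
                 tolerance = 1e-12)
  }

  all5 <- normalizeToMedian(rep(5, 4), c(5, 10))
  expect_equal(all5$ratios, c(1, 2))

  expect_error(normalizeToMedian(numeric(0)), "non-empty")
  expect_error(normalizeToMedian(c(0, 0, 0)), "zero")
})

test_that("dose screening is the intake times the e(g) coefficient", {
  expect_equal(doseScreening(100), 110e-6)   # 110 uSv at 1.1 uSv/Bq
  expect_equal(doseScreening(0), 0)
  expect_equal(doseScreening(c(1, 2, 4)), c(1, 2, 4) * 1.1e-6)
  expect_equal(doseScreening(50, doseCoefficient = 0.018e-6),
               0.9e-6)  # a beta emitter's coefficient for comparison
  expect_error(doseScreening(-1), ">= 0")
  expect_error(doseScreening(1, doseCoefficient = 0), "> 0")
})
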