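test_that("tracer recovery is tracer counts over expected counts at full yield", {
  r <- refRecord(countsTracer = 345600 * 0.25 * 0.1, liveTime = 345600,
                 tracerActivity = 0.1, efficiency = 0.25,
                 bkgCountsTracer = 0)
  expect_equal(tracerRecovery(r), 1.0)

  r2 <- refRecord(countsTracer = 6048, liveTime = 345600,
                  tracerActivity = 0.1, efficiency = 0.25)
  expect_equal(tracerRecovery(r2), 0.70)
  # net-count variant subtracts the detector background
  expect_equal(tracerRecovery(r2, netCounts = TRUE),
               (6048 - 3.456) / (345600 * 0.25 * 0.1))

  expect_error(tracerRecovery(refRecord()), "efficiency")
})

test_that("per-blank K constant in net and as-printed modes", {
  b <- refBlank()  # gross 70, B*t = 3, A_tr = 0.05, N_tr = 4000
  expect_equal(kSingle(b), 67 * 0.05 / 3997, tolerance = 1e-12)
  expect_equal(kSingle(b), 8.381e-4, tolerance = 1e-4)
  expect_equal(kSingle(b, "as_printed"), 73 * 0.05 / 3997,
               tolerance = 1e-12)
  expect_equal(kSingle(b, "as_printed"), 9.132e-4, tolerance = 1e-4)

  clean <- refBlank(counts210Po = 0, bkgCounts210Po = 0)
  expect_equal(kSingle(clean), 0)
  # net mode clamps at zero when background exceeds the gross counts
  low <- refBlank(counts210Po = 1, bkgCounts210Po = 5)
  expect_equal(kSingle(low), 0)

  dead <- refBlank(countsTracer = 2, bkgCountsTracer = 10)
  expect_error(kSingle(dead), "net tracer")
})

test_that("K aggregation: mean, spread-based uncertainty and single-blank default", {
  b1 <- refBlank(); b2 <- refBlank(counts210Po = 90)
  K <- kAggregate(list(b1, b2))
  expect_equal(K@K, mean(c(kSingle(b1), kSingle(b2))))
  expect_equal(K@uKRel,
               sd(c(kSingle(b1), kSingle(b2))) / (K@K * sqrt(2)))
  expect_identical(K@nBlanks, 2L)

  solo <- kAggregate(list(b1), uKRelDefault = 0.25)
  expect_equal(solo@K, kSingle(b1))
  expect_equal(solo@uKRel, 0.25)

  same <- kAggregate(list(b1, b1, b1))
  expect_equal(same@uKRel, 0)

  med <- kAggregate(list(b1, b2, b2), aggregate = "median")
  expect_equal(med@K, kSingle(b2))

  expect_error(kAggregate(list()), "non-empty")
})

test_that("K and blank-equivalent counts round-trip to the blank's net counts", {
  # identity: kSingle (net) then N' under the blank's own conditions
  set.seed(31)
  for (i in 1:25) {
    b <- randomBlank()
    ki <- kSingle(b)
    rec <- measurementRecord(counts210Po = 0,
                             countsTracer = b@countsTracer,
                             liveTime = b@liveTime,
                             tracerActivity = b@tracerActivity,
                             aliquotVolume = 0.5,
                             bkgRateTracer = b@bkgRateTracer)
    nprime <- blankEquivalentCounts(ki, rec)
    net <- max(b@counts210Po - b@bkgRate210Po * b@liveTime, 0)
    expect_equal(nprime, net, tolerance = 1e-9)
  }

  r <- refRecord()
  expect_equal(blankEquivalentCounts(0, r), 0)
  # linear in the net tracer counts
  r2 <- refRecord(countsTracer = 2 * 4000 - 3.456)
  expect_equal(blankEquivalentCounts(1e-3, r2),
               2 * blankEquivalentCounts(1e-3, r), tolerance = 1e-12)
})

test_that("activity concentration follows the tracer-normalized balance", {
  r <- refRecord()
  K20 <- 20 * 0.05 / (4000 - 3.456)  # K giving N' = 20 for this record
  expect_equal(activityConcentration(r, K20), 0.0119239,
               tolerance = 1e-5)

  # balance point: gross analyte equals blank-equivalent + background
  rb <- refRecord(counts210Po = 20 + 3.456)
  expect_equal(activityConcentration(rb, K20), 0, tolerance = 1e-12)

  # halving the aliquot volume doubles the concentration
  rh <- refRecord(aliquotVolume = 0.25)
  expect_equal(activityConcentration(rh, K20),
               2 * activityConcentration(r, K20))

  # negative results are reported, not clamped
  rn <- refRecord(counts210Po = 5)
  expect_lt(activityConcentration(rn, K20), 0)
})

test_that("decay correction rescales by back-decay and in-count decay factors", {
  r <- refRecord()
  lam <- po210DecayConstantPerDay()
  tDays <- 518400 / 86400
  during <- lam * tDays / (1 - exp(-lam * tDays))
  plain <- activityConcentration(r, 0)
  corr <- activityConcentration(r, 0, decayCorrect = TRUE,
                                delayDays = po210HalfLifeDays())
  expect_equal(corr / plain, 2 * during, tolerance = 1e-12)
  expect_gt(during, 1)
})

test_that("MDC: Currie form magnitude, zero-background limit, monotonicity in time", {
  r <- refRecord()
  K67 <- 67 * 0.05 / (4000 - 3.456)
  expect_equal(mdc(r, K67), 1.0538e-3, tolerance = 1e-4)
  expect_gt(mdc(r, K67, "as_printed"), 5 * mdc(r, K67))

  r0 <- refRecord(bkgCounts210Po = 0, bkgCountsTracer = 0)
  expect_equal(mdc(r0, 0), 3 * 0.05 / (0.5 * 4000), tolerance = 1e-12)
  # eliminating N' gives the blank-style MDC driven by detector background
  expect_equal(mdc(r, K67, includeReagentBlank = FALSE),
               (4.66 * sqrt(3.456) + 3) * 0.05 / (0.5 * (4000 - 3.456)),
               tolerance = 1e-12)

  # counting 4x longer at fixed rates lowers the MDC
  t1 <- 518400
  rate <- list(tr = 4000 / t1, b = 3.456 / t1)
  mk <- function(t) measurementRecord(500, rate$tr * t, t, 0.05, 0.5,
                                      bkgRate210Po = rate$b,
                                      bkgRateTracer = rate$b)
  Kc <- kConstant(K67, 0.1, 5)
  expect_lt(mdc(mk(4 * t1), Kc), mdc(mk(t1), Kc))
})

test_that("uncertainty budget combines in quadrature and matches the reported U", {
  expect_equal(combinedUncertainty(c(0.03, 0.04, 0, 0, 0)), 0.05)
  expect_equal(combinedUncertainty(rep(0, 5)), 0)
  expect_equal(combinedUncertainty(0.07), 0.07)
  expect_error(combinedUncertainty(c(0.1, -0.1)), ">= 0")

  expect_equal(expandedUncertainty(1, 0.05), 0.1)
  expect_equal(expandedUncertainty(0.3, 0), 0)
  # consistency with a reported 0.475 +/- 0.12 Bq/l (k = 2) result
  expect_equal(round(expandedUncertainty(0.475, 0.1263), 2), 0.12)

  r <- refRecord(counts210Po = 1100)
  K <- kConstant(8.4e-4, 0.12, 5)
  budget <- uncertaintyBudget(r, K)
  expect_named(budget, c("countsAnalyte", "countsTracer", "tracerActivity",
                         "tracerMass", "blank"))
  nprime <- blankEquivalentCounts(K, r)
  netA <- 1100 - nprime - 3.456
  expect_equal(unname(budget["countsAnalyte"]), sqrt(1100) / netA)
  expect_equal(unname(budget["blank"]), 0.12 * nprime / netA)
  expect_gte(min(budget), 0)
})

test_that("analyzeSample bundles a self-consistent ActivityResult", {
  r <- refRecord(counts210Po = 1100, efficiency = 0.25,
                 sampleId = "S001")
  K <- kAggregate(list(refBlank(), refBlank(counts210Po = 60)))
  res <- analyzeSample(r, K)
  expect_s4_class(res, "ActivityResult")
  expect_true(validObject(res))
  expect_equal(res@expanded, 2 * res@uRel * res@concentration)
  expect_equal(res@concentration, activityConcentration(r, K))
  expect_equal(res@mdc, mdc(r, K))
  expect_equal(res@recovery, tracerRecovery(r))
  expect_identical(res@belowMdc, res@concentration < res@mdc)

  # below-detection sample: negative C reported, uncertainties undefined
  low <- refRecord(counts210Po = 10, efficiency = 0.25)
  resLow <- analyzeSample(low, K)
  expect_true(resLow@belowMdc)
  expect_true(is.na(resLow@uRel))
  expect_lt(resLow@concentration, resLow@mdc)
})
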