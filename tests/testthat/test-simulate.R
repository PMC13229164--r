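test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(seed = 7L)
  expect_identical(counts(simulateSpectrum(cfg)),
                   counts(simulateSpectrum(cfg)))
  c1 <- simulateCampaign(cfg, 4, 2)
  c2 <- simulateCampaign(cfg, 4, 2)
  expect_identical(vapply(c1$samples, slot, 0, "counts210Po"),
                   vapply(c2$samples, slot, 0, "counts210Po"))
  expect_identical(c1$truth$recovery, c2$truth$recovery)
})

test_that("a source-free analyte region stays empty", {
  cfg <- simulationConfig(trueC = 0, reagentBlankRate = 0,
                          bkgRate210Po = 0, bkgRateTracer = 0, seed = 3L)
  sp <- simulateSpectrum(cfg)
  pk <- integrateROI(sp, defaultROIs()$analyte)
  expect_equal(pk@grossCounts, 0)
})

test_that("simulated tracer peak area follows Poisson counting statistics", {
  cfg <- simulationConfig(tracerActivity = 0.1, liveTime = 345600,
                          efficiency = 0.25, recoverySd = 0,
                          reagentBlankRate = 0, bkgRate210Po = 0,
                          bkgRateTracer = 0, seed = 13L)
  sp <- simulateSpectrum(cfg, recovery = 1.0)
  gross <- integrateROI(sp, defaultROIs()$tracer)@grossCounts
  expect_lt(abs(gross - 8640), 3 * sqrt(8640))
})

test_that("simulated blanks reproduce the observed reagent-count level", {
  cfg <- simulationConfig(seed = 17L)
  camp <- simulateCampaign(cfg, 1, 60)
  blankCounts <- vapply(camp$blanks, slot, 0, "counts210Po")
  # per-blank variance = Poisson + recovery spread around 65 expected counts
  v <- 65 + (65 * cfg@recoverySd / cfg@recoveryMean)^2
  expect_lt(abs(mean(blankCounts) - 65), 3 * sqrt(v / 60))
})

test_that("a campaign without blanks is flagged", {
  cfg <- simulationConfig(seed = 19L)
  expect_warning(camp <- simulateCampaign(cfg, 2, 0), "K constant")
  expect_false(camp$kAvailable)
  expect_length(camp$blanks, 0)
})

test_that("estimated concentration is efficiency invariant up to Poisson scatter", {
  # E and R cancel from the activity equation; only counting scatter differs
  for (eff in c(0.1, 0.3)) {
    cfg <- simulationConfig(efficiency = eff, seed = 23L)
    camp <- simulateCampaign(cfg, 60, 5)
    K <- kAggregate(camp$blanks)
    ch <- vapply(camp$samples, activityConcentration, 0, K = K)
    se <- sd(ch) / sqrt(length(ch))
    expect_lt(abs(mean(ch) - 0.022), 3 * se)
  }
})

test_that("spectrum-level campaign recovers the truth end to end", {
  cfg <- simulationConfig(seed = 29L)
  camp <- simulateCampaign(cfg, 40, 5, spectra = TRUE)
  K <- kAggregate(camp$blanks)
  ch <- vapply(camp$samples, activityConcentration, 0, K = K)
  se <- sd(ch) / sqrt(length(ch))
  expect_lt(abs(mean(ch) - cfg@trueC), 3 * se)
  # recoveries used in simulation are recovered from the tracer peak
  rec <- vapply(camp$samples, tracerRecovery, 0)
  expect_equal(rec, camp$truth$recovery, tolerance = 0.1)
})

test_that("blank-only campaigns center on zero concentration with net-mode K", {
  cfg <- simulationConfig(trueC = 0, seed = 37L)
  camp <- simulateCampaign(cfg, 80, 8)
  K <- kAggregate(camp$blanks)
  ch <- vapply(camp$samples, activityConcentration, 0, K = K)
  # the K estimate is shared by all samples, so the SE of the mean carries
  # its uncertainty in addition to the per-sample scatter
  se <- sqrt(var(ch) / length(ch) +
               (K@uKRel * K@K / cfg@aliquotVolume)^2)
  expect_lt(abs(mean(ch)), 3 * se)
})
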