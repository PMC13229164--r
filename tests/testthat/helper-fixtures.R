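# shared fixtures: reference counting conditions used across the assay
# tests (multi-day count, ~0.05 Bq tracer, 0.5 l aliquot) and generators
# for random blanks and deterministic Gaussian spectra

refRecord <- function(counts210Po = 500, countsTracer = 4000,
                      liveTime = 518400, tracerActivity = 0.05,
                      aliquotVolume = 0.5,
                      bkgCounts210Po = 3.456, bkgCountsTracer = 3.456,
                      ...) {
  measurementRecord(counts210Po = counts210Po,
                    countsTracer = countsTracer, liveTime = liveTime,
                    tracerActivity = tracerActivity,
                    aliquotVolume = aliquotVolume,
                    bkgRate210Po = bkgCounts210Po / liveTime,
                    bkgRateTracer = bkgCountsTracer / liveTime, ...)
}

refBlank <- function(counts210Po = 70, countsTracer = 4000,
                     tracerActivity = 0.05, liveTime = 518400,
                     bkgCounts210Po = 3, bkgCountsTracer = 3, ...) {
  blankMeasurement(counts210Po = counts210Po,
                   countsTracer = countsTracer,
                   tracerActivity = tracerActivity, liveTime = liveTime,
                   bkgRate210Po = bkgCounts210Po / liveTime,
                   bkgRateTracer = bkgCountsTracer / liveTime, ...)
}

randomBlank <- function() {
  t <- runif(1, 3e5, 7e5)
  blankMeasurement(counts210Po = rpois(1, 65) + 5,
                   countsTracer = rpois(1, 4500) + 100,
                   tracerActivity = runif(1, 0.02, 0.1),
                   liveTime = t,
                   bkgRate210Po = runif(1, 0, 4) / t,
                   bkgRateTracer = runif(1, 0, 4) / t)
}

# noise-free Gaussian peak spectrum: expected counts rounded to integers
gaussSpectrum <- function(area, e0, sigmaKeV, slopeKeV = 1,
                          nChannels = 2001L, liveTime = 1000) {
  centers <- slopeKeV * (0:(nChannels - 1L))
  mu <- area * (pnorm(centers + slopeKeV / 2, e0, sigmaKeV) -
                  pnorm(centers - slopeKeV / 2, e0, sigmaKeV))
  alphaSpectrum(round(mu), liveTime = liveTime,
                calibration = energyCalibration(slopeKeV, 0))
}
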