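# Synthetic-data generator: Poisson alpha spectra and whole measurement
# campaigns with known truth. Counting noise is Poisson per channel; peak
# shapes are pure Gaussian (an exponential low-energy tail can be enabled);
# no electronic-noise model, since only count statistics enter the
# calculation chain.

#' Construct a SimulationConfig
#'
#' @param trueC True 210Po activity concentration, Bq/l (default 0.022, the
#'   validation level).
#' @param aliquotVolume Analyzed aliquot volume, litres (default 0.5).
#' @param liveTime Live counting time, s (default 518400 = 6 days).
#' @param tracerActivity Added tracer activity, Bq (default 0.0489, i.e.
#'   0.1 g of the 0.4891 Bq/g tracer solution).
#' @param efficiency Counting efficiency (default 0.25, typical for a PIPS
#'   detector at close geometry).
#' @param recoveryMean,recoverySd Tracer-recovery distribution (default
#'   0.714 and 0.079, truncated to (0, 1]).
#' @param reagentBlankRate Expected reagent-derived 210Po counts per second
#'   under the reference conditions, default 65 counts per 6-day count.
#' @param bkgRate210Po,bkgRateTracer Detector background count rates per
#'   ROI, 1/s (default 3e-6, i.e. a couple of counts per week).
#' @param fwhm Peak FWHM, keV (default 20, inside the 24 keV QC bound).
#' @param peakEnergies Named alpha-line energies, keV.
#' @param nChannels,slope,intercept Spectrum axis (default 1024 channels at
#'   6 keV/channel from 0 keV).
#' @param seed Integer seed (`NA`: use the current RNG state).
#' @param tailFraction Fraction of each peak's area diverted into an
#'   exponential low-energy tail (default 0 = pure Gaussian).
#' @param tailScale Decay length of that tail, keV.
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(seed = 1)
#' @export
simulationConfig <- function(trueC = 0.022, aliquotVolume = 0.5,
                             liveTime = 518400, tracerActivity = 0.0489,
                             efficiency = 0.25, recoveryMean = 0.714,
                             recoverySd = 0.079,
                             reagentBlankRate = 65 / 518400,
                             bkgRate210Po = 3e-6, bkgRateTracer = 3e-6,
                             fwhm = 20, peakEnergies = poAlphaLines(),
                             nChannels = 1024L, slope = 6, intercept = 0,
                             seed = NA_integer_, tailFraction = 0,
                             tailScale = 15) {
  cfg <- new("SimulationConfig", trueC = as.numeric(trueC),
             aliquotVolume = as.numeric(aliquotVolume),
             liveTime = as.numeric(liveTime),
             tracerActivity = as.numeric(tracerActivity),
             efficiency = as.numeric(efficiency),
             recoveryMean = as.numeric(recoveryMean),
             recoverySd = as.numeric(recoverySd),
             reagentBlankRate = as.numeric(reagentBlankRate),
             bkgRate210Po = as.numeric(bkgRate210Po),
             bkgRateTracer = as.numeric(bkgRateTracer),
             fwhm = as.numeric(fwhm), peakEnergies = peakEnergies,
             nChannels = as.integer(nChannels), slope = as.numeric(slope),
             intercept = as.numeric(intercept), seed = as.integer(seed))
  attr(cfg, "tailFraction") <- tailFraction
  attr(cfg, "tailScale") <- tailScale
  cfg
}

# reagent 210Po expressed as an activity (Bq): the configured count rate is
# referenced to this configuration's own efficiency and mean recovery
.reagentActivity <- function(config) {
  config@reagentBlankRate / (config@efficiency * config@recoveryMean)
}

.drawRecovery <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      r <- stats::rnorm(1, mean, sd)
      if (r > 0 && r <= 1) break
    }
    out[i] <- r
  }
  out
}

# expected counts per channel for one source; background is a flat
# continuum whose rate integrated over a 100 keV window equals the
# configured per-ROI rate
.expectedChannels <- function(config, recovery, kind) {
  n <- config@nChannels
  centers <- config@intercept + config@slope * (0:(n - 1L))
  edgesLo <- centers - config@slope / 2
  edgesHi <- centers + config@slope / 2
  sigma <- config@fwhm / (2 * sqrt(2 * log(2)))
  t <- config@liveTime
  eff <- config@efficiency * recovery
  tracerArea <- if (kind == "disc") 0 else config@tracerActivity * t * eff
  analyteArea <- switch(kind,
    sample = (config@trueC * config@aliquotVolume +
                .reagentActivity(config)) * t * eff,
    blank = .reagentActivity(config) * t * eff,
    disc = 0)
  tailFrac <- attr(config, "tailFraction")
  if (is.null(tailFrac)) tailFrac <- 0
  tailScale <- attr(config, "tailScale")
  if (is.null(tailScale)) tailScale <- 15
  peak <- function(area, e0) {
    if (area == 0) return(numeric(n))
    core <- area * (1 - tailFrac) *
      (stats::pnorm(edgesHi, e0, sigma) - stats::pnorm(edgesLo, e0, sigma))
    if (tailFrac > 0) {
      # exponential tail below the line: density (1/s) exp((e - e0)/s), e < e0
      lo <- pmin(edgesLo, e0); hi <- pmin(edgesHi, e0)
      core <- core + area * tailFrac *
        (exp((hi - e0) / tailScale) - exp((lo - e0) / tailScale))
    }
    core
  }
  mu <- peak(tracerArea, config@peakEnergies[["tracer"]]) +
    peak(analyteArea, config@peakEnergies[["analyte"]])
  mu + config@bkgRate210Po * t * config@slope / 100
}

#' Simulate one alpha spectrum
#'
#' Expected channel counts are two Gaussian peaks — tracer area
#' `A_tr * t * E * R` and analyte area `(C * V) * t * E * R` plus the
#' reagent 210Po — on a flat detector-background continuum, sampled
#' channel-wise as Poisson counting noise. Deterministic under a fixed
#' seed.
#'
#' @param config A [SimulationConfig-class].
#' @param kind `"sample"` (tracer + analyte + reagent), `"blank"` (tracer +
#'   reagent only) or `"disc"` (bare-disc background check).
#' @param recovery Fixed tracer recovery for this spectrum; `NULL` draws
#'   one from the configured distribution.
#' @param seed Seed for this spectrum; defaults to the config's seed, `NA`
#'   to use the current RNG state.
#' @return A calibrated [AlphaSpectrum-class].
#' @examples
#' sp <- simulateSpectrum(simulationConfig(seed = 7L))
#' sp
#' @export
simulateSpectrum <- function(config, kind = c("sample", "blank", "disc"),
                             recovery = NULL, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  kind <- match.arg(kind)
  if (!is.na(seed)) set.seed(seed)
  if (is.null(recovery))
    recovery <- .drawRecovery(1, config@recoveryMean, config@recoverySd)
  .checkScalar(recovery, "recovery", positive = TRUE)
  mu <- .expectedChannels(config, recovery, kind)
  sp <- alphaSpectrum(stats::rpois(config@nChannels, mu),
                      liveTime = config@liveTime,
                      detectorId = "SIM",
                      calibration = energyCalibration(config@slope,
                                                      config@intercept))
  attr(sp, "recovery") <- recovery
  sp
}

#' Simulate a full measurement campaign with known truth
#'
#' Draws `nSamples` analytical samples at the configured true concentration
#' and `nBlanks` full-procedure blanks (reagent contamination only), each
#' with its own tracer recovery from the truncated-normal recovery
#' distribution. By default ROI-level gross counts are drawn directly as
#' Poisson totals; with `spectra = TRUE` full spectra are generated and
#' integrated over [defaultROIs()], exercising the spectrum path
#' end-to-end. All truth (recoveries, true concentration, seed) is retained
#' for assertions.
#'
#' @param config A [SimulationConfig-class]; its `seed` (when not `NA`)
#'   seeds the campaign's single pseudo-random stream.
#' @param nSamples Number of analytical samples (>= 1).
#' @param nBlanks Number of blanks (0 leaves K unavailable and flags the
#'   campaign with a warning).
#' @param spectra Also generate and integrate full spectra.
#' @return A list with `samples` (list of [MeasurementRecord-class]),
#'   `blanks` (list of [BlankMeasurement-class]), `truth` (data.frame with
#'   `sampleId`, `recovery`, `trueC`), `spectra`/`blankSpectra` (when
#'   requested), `kAvailable`, and the `config`.
#' @examples
#' camp <- simulateCampaign(simulationConfig(seed = 1L), 3, 2)
#' camp$truth
#' @export
simulateCampaign <- function(config, nSamples, nBlanks = 5L,
                             spectra = FALSE) {
  stopifnot(is(config, "SimulationConfig"))
  if (nSamples < 1L) stop("'nSamples' must be >= 1", call. = FALSE)
  if (nBlanks < 0L) stop("'nBlanks' must be >= 0", call. = FALSE)
  if (!is.na(config@seed)) set.seed(config@seed)
  t <- config@liveTime
  eff <- config@efficiency
  rois <- defaultROIs(lines = config@peakEnergies)

  makeOne <- function(kind, id, recovery) {
    if (spectra) {
      sp <- simulateSpectrum(config, kind = kind, recovery = recovery,
                             seed = NA_integer_)
      nAn <- integrateROI(sp, rois$analyte)@grossCounts
      nTr <- integrateROI(sp, rois$tracer)@grossCounts
    } else {
      er <- eff * recovery
      muTr <- config@tracerActivity * t * er + config@bkgRateTracer * t
      muAn <- switch(kind,
        sample = (config@trueC * config@aliquotVolume +
                    .reagentActivity(config)) * t * er,
        blank = .reagentActivity(config) * t * er) +
        config@bkgRate210Po * t
      nAn <- stats::rpois(1, muAn)
      nTr <- stats::rpois(1, muTr)
      sp <- NULL
    }
    list(nAn = nAn, nTr = nTr, spectrum = sp)
  }

  recS <- .drawRecovery(nSamples, config@recoveryMean, config@recoverySd)
  samples <- vector("list", nSamples)
  sampleSpectra <- if (spectra) vector("list", nSamples) else NULL
  ids <- sprintf("S%03d", seq_len(nSamples))
  for (i in seq_len(nSamples)) {
    one <- makeOne("sample", ids[i], recS[i])
    samples[[i]] <- measurementRecord(
      counts210Po = one$nAn, countsTracer = one$nTr, liveTime = t,
      tracerActivity = config@tracerActivity,
      aliquotVolume = config@aliquotVolume,
      bkgRate210Po = config@bkgRate210Po,
      bkgRateTracer = config@bkgRateTracer,
      efficiency = eff, sampleId = ids[i])
    if (spectra) sampleSpectra[[i]] <- one$spectrum
  }

  blanks <- list(); blankSpectra <- NULL; recB <- numeric(0)
  if (nBlanks > 0L) {
    recB <- .drawRecovery(nBlanks, config@recoveryMean, config@recoverySd)
    blanks <- vector("list", nBlanks)
    blankSpectra <- if (spectra) vector("list", nBlanks) else NULL
    for (i in seq_len(nBlanks)) {
      one <- makeOne("blank", i, recB[i])
      blanks[[i]] <- blankMeasurement(
        counts210Po = one$nAn, countsTracer = one$nTr,
        tracerActivity = config@tracerActivity, liveTime = t,
        bkgRate210Po = config@bkgRate210Po,
        bkgRateTracer = config@bkgRateTracer,
        blankId = sprintf("B%03d", i))
      if (spectra) blankSpectra[[i]] <- one$spectrum
    }
  } else {
    warning("campaign has no blanks: K constant unavailable", call. = FALSE)
  }

  list(samples = samples, blanks = blanks,
       truth = data.frame(sampleId = ids, recovery = recS,
                          trueC = config@trueC),
       blankRecoveries = recB,
       spectra = sampleSpectra, blankSpectra = blankSpectra,
       kAvailable = nBlanks > 0L, config = config)
}
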