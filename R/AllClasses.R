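#' @import methods
NULL

# ---------------------------------------------------------------------------
# EnergyCalibration

#' Linear energy calibration of an alpha spectrometer channel axis
#'
#' Maps channel numbers (0-based, channel centers) to alpha-particle energy
#' in keV via `energy = intercept + slope * channel`. Obtained from
#' [calibrateEnergy()] on a multi-line calibration source, or read from the
#' `$ENER_FIT` block of an SPE file.
#'
#' @slot slope keV per channel, > 0 (energy strictly increasing).
#' @slot intercept keV at channel 0.
#' @slot residuals Fit residuals (keV) of the calibration points, empty when
#'   the calibration was not fitted.
#'
#' @aliases EnergyCalibration
#' @seealso [calibrateEnergy()], [channelEnergies()]
#' @export
setClass("EnergyCalibration",
  slots = c(slope = "numeric", intercept = "numeric", residuals = "numeric"))

setValidity("EnergyCalibration", function(object) {
  msg <- character(0)
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "'slope' must be a single finite value > 0 (keV/channel)")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "'intercept' must be a single finite value (keV)")
  if (length(msg)) msg else TRUE
})

#' Construct an EnergyCalibration
#'
#' @param slope keV per channel (> 0).
#' @param intercept keV at channel 0.
#' @param residuals Optional fit residuals in keV.
#' @return An [EnergyCalibration-class] object.
#' @examples
#' energyCalibration(slope = 6, intercept = 0)
#' @export
energyCalibration <- function(slope, intercept, residuals = numeric(0)) {
  new("EnergyCalibration", slope = as.numeric(slope),
      intercept = as.numeric(intercept), residuals = as.numeric(residuals))
}

setClassUnion("OptionalCalibration", c("EnergyCalibration", "NULL"))

setMethod("show", "EnergyCalibration", function(object) {
  cat(sprintf("EnergyCalibration: E(ch) = %.6g + %.6g * ch keV\n",
              object@intercept, object@slope))
  if (length(object@residuals))
    cat(sprintf("  fit residuals (keV): max |r| = %.3g over %d points\n",
                max(abs(object@residuals)), length(object@residuals)))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# AlphaSpectrum

#' An alpha-particle spectrum
#'
#' A channel/count histogram recorded on a silicon (PIPS) detector, together
#' with the live counting time and, optionally, an energy calibration.
#' Channels are 0-based, matching the `$DATA first last` convention of the
#' IAEA SPE ASCII format; energies refer to channel centers.
#'
#' @slot detectorId Detector identifier (free text, may be empty).
#' @slot counts Integer vector of channel counts, all >= 0, length >= 2.
#' @slot liveTime Live counting time in seconds, > 0.
#' @slot acquisitionStart Acquisition start timestamp as ISO-8601 text, or
#'   `NA` when unknown.
#' @slot calibration An [EnergyCalibration-class] or `NULL` when the
#'   spectrum is uncalibrated.
#'
#' @aliases AlphaSpectrum
#' @seealso [alphaSpectrum()], [readSpectrum()], [integrateROI()]
#' @export
setClass("AlphaSpectrum",
  slots = c(detectorId = "character", counts = "integer",
            liveTime = "numeric", acquisitionStart = "character",
            calibration = "OptionalCalibration"))

setValidity("AlphaSpectrum", function(object) {
  msg <- character(0)
  if (length(object@counts) < 2L)
    msg <- c(msg, "a spectrum needs at least 2 channels")
  if (anyNA(object@counts) || any(object@counts < 0L))
    msg <- c(msg, "all channel counts must be non-negative integers")
  if (length(object@liveTime) != 1L || !is.finite(object@liveTime) ||
      object@liveTime <= 0)
    msg <- c(msg, "'liveTime' must be a single finite value > 0 (s)")
  if (length(object@detectorId) != 1L)
    msg <- c(msg, "'detectorId' must be a single string")
  if (length(object@acquisitionStart) != 1L)
    msg <- c(msg, "'acquisitionStart' must be a single string or NA")
  if (length(msg)) msg else TRUE
})

#' Construct an AlphaSpectrum
#'
#' @param counts Vector of non-negative whole-number channel counts
#'   (length >= 2); channel numbers are implicitly `0:(length(counts) - 1)`.
#' @param liveTime Live counting time, seconds (> 0).
#' @param detectorId Detector identifier.
#' @param acquisitionStart Optional ISO-8601 timestamp text.
#' @param calibration Optional [EnergyCalibration-class].
#' @return An [AlphaSpectrum-class] object.
#' @examples
#' sp <- alphaSpectrum(c(0, 5, 10, 5, 0), liveTime = 3600,
#'                     calibration = energyCalibration(6, 0))
#' sp
#' @export
alphaSpectrum <- function(counts, liveTime, detectorId = "",
                          acquisitionStart = NA_character_,
                          calibration = NULL) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || !all(.isWholeNumber(counts)))
    stop("channel counts must be whole numbers", call. = FALSE)
  new("AlphaSpectrum", detectorId = as.character(detectorId),
      counts = as.integer(round(counts)), liveTime = as.numeric(liveTime),
      acquisitionStart = as.character(acquisitionStart),
      calibration = calibration)
}

setMethod("show", "AlphaSpectrum", function(object) {
  cat(sprintf("AlphaSpectrum: %d channels, %d total counts, live time %.6g s\n",
              length(object@counts), sum(object@counts), object@liveTime))
  if (nzchar(object@detectorId))
    cat("  detector:", object@detectorId, "\n")
  if (!is.null(object@calibration))
    cat(sprintf("  calibrated: E(ch) = %.6g + %.6g * ch keV\n",
                object@calibration@intercept, object@calibration@slope))
  else cat("  uncalibrated\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# RegionOfInterest / PeakSummary

#' Energy region of interest
#'
#' A half-open energy window `[eLow, eHigh)` (keV) labelling one isotope's
#' alpha peak. A channel contributes to the ROI when its center energy falls
#' inside the window, which makes ROI integration exactly additive under any
#' split of the window.
#'
#' @slot label Isotope tag, conventionally `"tracer"` (209Po) or
#'   `"analyte"` (210Po).
#' @slot eLow,eHigh Window bounds in keV, `eLow < eHigh`.
#'
#' @aliases RegionOfInterest
#' @seealso [roi()], [defaultROIs()], [integrateROI()]
#' @export
setClass("RegionOfInterest",
  slots = c(label = "character", eLow = "numeric", eHigh = "numeric"))

setValidity("RegionOfInterest", function(object) {
  msg <- character(0)
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "'label' must be a single string")
  if (length(object@eLow) != 1L || length(object@eHigh) != 1L ||
      !is.finite(object@eLow) || !is.finite(object@eHigh) ||
      object@eLow >= object@eHigh)
    msg <- c(msg, "need finite eLow < eHigh (keV)")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionOfInterest
#'
#' @param label Isotope tag (e.g. `"tracer"`, `"analyte"`).
#' @param eLow,eHigh Window bounds in keV (half-open, `eLow < eHigh`).
#' @return A [RegionOfInterest-class] object.
#' @examples
#' roi("analyte", 5244.3, 5344.3)
#' @export
roi <- function(label, eLow, eHigh) {
  new("RegionOfInterest", label = as.character(label),
      eLow = as.numeric(eLow), eHigh = as.numeric(eHigh))
}

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("ROI '%s': [%.6g, %.6g) keV\n",
              object@label, object@eLow, object@eHigh))
  invisible(NULL)
})

#' Summary of a spectral peak within an ROI
#'
#' Result of [integrateROI()]: the gross counts, the count-weighted centroid
#' and the full width at half maximum obtained by linear interpolation at
#' half the modal-bin height. Centroid and FWHM are `NA` when the ROI is
#' empty or the half-maximum crossings fall outside the window.
#'
#' @slot label ROI label the summary refers to.
#' @slot grossCounts Total counts in the window (>= 0).
#' @slot centroid Count-weighted mean energy, keV (`NA` if empty).
#' @slot fwhm Full width at half maximum, keV (`NA` when undefined).
#'
#' @aliases PeakSummary
#' @export
setClass("PeakSummary",
  slots = c(label = "character", grossCounts = "numeric",
            centroid = "numeric", fwhm = "numeric"))

setValidity("PeakSummary", function(object) {
  msg <- character(0)
  if (length(object@grossCounts) != 1L || is.na(object@grossCounts) ||
      object@grossCounts < 0)
    msg <- c(msg, "'grossCounts' must be a single value >= 0")
  if (!is.na(object@fwhm) && object@fwhm <= 0)
    msg <- c(msg, "'fwhm' must be > 0 when defined")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PeakSummary", function(object) {
  cat(sprintf("PeakSummary '%s': gross %.6g counts, centroid %s keV, FWHM %s keV\n",
              object@label, object@grossCounts,
              ifelse(is.na(object@centroid), "NA",
                     sprintf("%.2f", object@centroid)),
              ifelse(is.na(object@fwhm), "NA", sprintf("%.2f", object@fwhm))))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# MeasurementRecord / BlankMeasurement

#' All quantities entering the activity-concentration calculation for one sample
#'
#' Gross ROI counts for analyte (210Po) and tracer (209Po), live counting
#' time, added tracer activity, per-detector background count rates in both
#' ROIs, analyzed aliquot volume and (optionally) the detector counting
#' efficiency needed for tracer recovery.
#'
#' @slot sampleId Sample identifier.
#' @slot counts210Po Gross counts in the analyte ROI (>= 0).
#' @slot countsTracer Gross counts in the tracer ROI (>= 0).
#' @slot liveTime Live counting time, s (> 0).
#' @slot tracerActivity Tracer (209Po) activity added to the sample, Bq (> 0).
#' @slot bkgRate210Po Detector background count rate in the analyte ROI, 1/s.
#' @slot bkgRateTracer Detector background count rate in the tracer ROI, 1/s.
#' @slot aliquotVolume Analyzed urine aliquot volume, litres (> 0).
#' @slot efficiency Detector counting efficiency (fraction, `NA` if unknown;
#'   required only for [tracerRecovery()]).
#'
#' @aliases MeasurementRecord
#' @seealso [measurementRecord()], [activityConcentration()], [mdc()]
#' @export
setClass("MeasurementRecord",
  slots = c(sampleId = "character", counts210Po = "numeric",
            countsTracer = "numeric", liveTime = "numeric",
            tracerActivity = "numeric", bkgRate210Po = "numeric",
            bkgRateTracer = "numeric", aliquotVolume = "numeric",
            efficiency = "numeric"))

.validCounting <- function(object) {
  msg <- character(0)
  if (object@counts210Po < 0 || object@countsTracer < 0)
    msg <- c(msg, "ROI counts must be >= 0")
  if (!is.finite(object@liveTime) || object@liveTime <= 0)
    msg <- c(msg, "'liveTime' must be > 0 (s)")
  if (!is.finite(object@tracerActivity) || object@tracerActivity <= 0)
    msg <- c(msg, "'tracerActivity' must be > 0 (Bq)")
  if (object@bkgRate210Po < 0 || object@bkgRateTracer < 0)
    msg <- c(msg, "background rates must be >= 0 (1/s)")
  msg
}

setValidity("MeasurementRecord", function(object) {
  msg <- .validCounting(object)
  if (!is.finite(object@aliquotVolume) || object@aliquotVolume <= 0)
    msg <- c(msg, "'aliquotVolume' must be > 0 (l)")
  if (!is.na(object@efficiency) &&
      (object@efficiency <= 0 || object@efficiency > 1))
    msg <- c(msg, "'efficiency' must be in (0, 1] when given")
  if (length(msg)) msg else TRUE
})

#' Construct a MeasurementRecord
#'
#' @param counts210Po,countsTracer Gross ROI counts (analyte / tracer).
#' @param liveTime Live counting time, s.
#' @param tracerActivity Added tracer activity, Bq.
#' @param aliquotVolume Analyzed aliquot volume, litres.
#' @param bkgRate210Po,bkgRateTracer Detector background count rates in the
#'   analyte and tracer ROIs, 1/s.
#' @param efficiency Optional counting efficiency (fraction).
#' @param sampleId Sample identifier.
#' @return A [MeasurementRecord-class] object.
#' @examples
#' measurementRecord(counts210Po = 500, countsTracer = 4000,
#'                   liveTime = 345600, tracerActivity = 0.05,
#'                   aliquotVolume = 0.5, bkgRate210Po = 1e-5,
#'                   bkgRateTracer = 1e-5)
#' @export
measurementRecord <- function(counts210Po, countsTracer, liveTime,
                              tracerActivity, aliquotVolume,
                              bkgRate210Po = 0, bkgRateTracer = 0,
                              efficiency = NA_real_, sampleId = "") {
  new("MeasurementRecord", sampleId = as.character(sampleId),
      counts210Po = as.numeric(counts210Po),
      countsTracer = as.numeric(countsTracer),
      liveTime = as.numeric(liveTime),
      tracerActivity = as.numeric(tracerActivity),
      bkgRate210Po = as.numeric(bkgRate210Po),
      bkgRateTracer = as.numeric(bkgRateTracer),
      aliquotVolume = as.numeric(aliquotVolume),
      efficiency = as.numeric(efficiency))
}

setMethod("show", "MeasurementRecord", function(object) {
  cat(sprintf(paste0("MeasurementRecord '%s': N(210Po) = %.6g, N(tracer) = %.6g,",
                     " t = %.6g s, A_tr = %.4g Bq, V = %.3g l\n"),
              object@sampleId, object@counts210Po, object@countsTracer,
              object@liveTime, object@tracerActivity, object@aliquotVolume))
  invisible(NULL)
})

#' A reagent-blank measurement with tracer
#'
#' One full-procedure blank (analyte-free matrix plus tracer): the gross ROI
#' counts, tracer activity, counting time and detector background rates that
#' enter the per-blank reagent constant (see [kSingle()]).
#'
#' @slot blankId Blank identifier.
#' @slot counts210Po Gross counts in the analyte ROI.
#' @slot countsTracer Gross counts in the tracer ROI.
#' @slot tracerActivity Tracer activity added to the blank, Bq.
#' @slot liveTime Counting time of the blank, s.
#' @slot bkgRate210Po,bkgRateTracer Detector background count rates, 1/s.
#'
#' @aliases BlankMeasurement
#' @seealso [blankMeasurement()], [kSingle()], [kAggregate()]
#' @export
setClass("BlankMeasurement",
  slots = c(blankId = "character", counts210Po = "numeric",
            countsTracer = "numeric", tracerActivity = "numeric",
            liveTime = "numeric", bkgRate210Po = "numeric",
            bkgRateTracer = "numeric"))

setValidity("BlankMeasurement", function(object) {
  msg <- .validCounting(object)
  if (length(msg)) msg else TRUE
})

#' Construct a BlankMeasurement
#'
#' @param counts210Po,countsTracer Gross ROI counts of the blank.
#' @param tracerActivity Tracer activity added to the blank, Bq.
#' @param liveTime Counting time of the blank, s.
#' @param bkgRate210Po,bkgRateTracer Detector background rates, 1/s.
#' @param blankId Identifier.
#' @return A [BlankMeasurement-class] object.
#' @examples
#' blankMeasurement(counts210Po = 70, countsTracer = 4000,
#'                  tracerActivity = 0.05, liveTime = 518400)
#' @export
blankMeasurement <- function(counts210Po, countsTracer, tracerActivity,
                             liveTime, bkgRate210Po = 0, bkgRateTracer = 0,
                             blankId = "") {
  new("BlankMeasurement", blankId = as.character(blankId),
      counts210Po = as.numeric(counts210Po),
      countsTracer = as.numeric(countsTracer),
      tracerActivity = as.numeric(tracerActivity),
      liveTime = as.numeric(liveTime),
      bkgRate210Po = as.numeric(bkgRate210Po),
      bkgRateTracer = as.numeric(bkgRateTracer))
}

setMethod("show", "BlankMeasurement", function(object) {
  cat(sprintf(paste0("BlankMeasurement '%s': N(210Po) = %.6g, N(tracer) = %.6g,",
                     " t = %.6g s, A_tr = %.4g Bq\n"),
              object@blankId, object@counts210Po, object@countsTracer,
              object@liveTime, object@tracerActivity))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# KConstant

#' Reagent-background constant derived from a blank series
#'
#' The constant K (Bq) summarizing the 210Po contamination introduced by the
#' reagents, estimated from a series of full-procedure blanks, together with
#' its relative standard uncertainty. K is normalized into blank-equivalent
#' counts N' for each analytical sample by [blankEquivalentCounts()].
#'
#' @slot K Reagent-background constant, Bq (>= 0 in net mode).
#' @slot uKRel Relative standard uncertainty of K (fraction).
#' @slot nBlanks Number of blanks in the series (>= 1).
#' @slot mode `"net"` (detector background subtracted per blank, default) or
#'   `"as_printed"` (background added, preserving the typeset formula).
#'
#' @aliases KConstant
#' @seealso [kAggregate()], [blankEquivalentCounts()]
#' @export
setClass("KConstant",
  slots = c(K = "numeric", uKRel = "numeric", nBlanks = "integer",
            mode = "character"))

setValidity("KConstant", function(object) {
  msg <- character(0)
  if (!is.finite(object@K))
    msg <- c(msg, "'K' must be finite (Bq)")
  if (identical(object@mode, "net") && isTRUE(object@K < 0))
    msg <- c(msg, "'K' must be >= 0 in net mode")
  if (!is.finite(object@uKRel) || object@uKRel < 0)
    msg <- c(msg, "'uKRel' must be >= 0")
  if (length(object@nBlanks) != 1L || is.na(object@nBlanks) ||
      object@nBlanks < 1L)
    msg <- c(msg, "'nBlanks' must be >= 1")
  if (!object@mode %in% c("net", "as_printed"))
    msg <- c(msg, "'mode' must be 'net' or 'as_printed'")
  if (length(msg)) msg else TRUE
})

#' Construct a KConstant directly
#'
#' Usually produced by [kAggregate()]; the constructor is exposed for
#' round-tripping stored results.
#'
#' @param K Reagent-background constant, Bq.
#' @param uKRel Relative standard uncertainty (fraction).
#' @param nBlanks Number of blanks behind the estimate.
#' @param mode `"net"` or `"as_printed"`.
#' @return A [KConstant-class] object.
#' @examples
#' kConstant(8.4e-4, uKRel = 0.1, nBlanks = 5)
#' @export
kConstant <- function(K, uKRel, nBlanks = 1L, mode = "net") {
  new("KConstant", K = as.numeric(K), uKRel = as.numeric(uKRel),
      nBlanks = as.integer(nBlanks), mode = as.character(mode))
}

setMethod("show", "KConstant", function(object) {
  cat(sprintf("KConstant: K = %.4g Bq (u_rel = %.1f%%, n = %d blanks, mode = %s)\n",
              object@K, 100 * object@uKRel, object@nBlanks, object@mode))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# ActivityResult

#' Reportable result for one analytical sample
#'
#' The 210Po activity concentration with its combined and expanded (k = 2)
#' uncertainties, the minimum detectable activity concentration, the tracer
#' recovery where computable, and the below-MDC flag. Negative
#' concentrations are reported as-is (not clamped) and flagged.
#'
#' @slot sampleId Sample identifier.
#' @slot concentration C_lab, Bq/l (may be negative).
#' @slot uRel Relative combined standard uncertainty (fraction; `NA` when the
#'   net analyte signal is non-positive).
#' @slot expanded Expanded uncertainty `U = 2 * uRel * C`, Bq/l (`NA` when
#'   `uRel` is undefined or `C <= 0`).
#' @slot mdc Minimum detectable activity concentration, Bq/l.
#' @slot recovery Tracer recovery (fraction, `NA` when efficiency unknown).
#' @slot belowMdc `TRUE` iff `concentration < mdc`.
#' @slot kValue The K constant (Bq) applied to this sample.
#' @slot configDigest Digest of the configuration used (text).
#'
#' @aliases ActivityResult
#' @seealso [analyzeSample()]
#' @export
setClass("ActivityResult",
  slots = c(sampleId = "character", concentration = "numeric",
            uRel = "numeric", expanded = "numeric", mdc = "numeric",
            recovery = "numeric", belowMdc = "logical", kValue = "numeric",
            configDigest = "character"))

setValidity("ActivityResult", function(object) {
  msg <- character(0)
  if (!is.finite(object@mdc) || object@mdc < 0)
    msg <- c(msg, "'mdc' must be finite and >= 0 (Bq/l)")
  if (!is.na(object@uRel) && object@uRel < 0)
    msg <- c(msg, "'uRel' must be >= 0")
  if (is.finite(object@concentration) && object@concentration > 0 &&
      !is.na(object@uRel) && !is.na(object@expanded)) {
    want <- 2 * object@uRel * object@concentration
    if (abs(object@expanded - want) >
        1e-9 * max(1, abs(want)))
      msg <- c(msg, "'expanded' must equal 2 * uRel * concentration")
  }
  if (!identical(object@belowMdc, object@concentration < object@mdc))
    msg <- c(msg, "'belowMdc' must equal (concentration < mdc)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ActivityResult", function(object) {
  cat(sprintf("ActivityResult '%s': C = %.4f Bq/l", object@sampleId,
              object@concentration))
  if (!is.na(object@expanded))
    cat(sprintf(" +/- %.4f (U, k = 2)", object@expanded))
  cat(sprintf(", MDC = %.4g Bq/l", object@mdc))
  if (!is.na(object@recovery))
    cat(sprintf(", R = %.1f%%", 100 * object@recovery))
  if (object@belowMdc) cat("  [< MDC]")
  cat("\n")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# IntercomparisonScore

#' Proficiency-test performance score
#'
#' A laboratory result compared with the organizer's assigned value through
#' the z-score, the relative bias (percent) and the En number; see
#' [intercomparisonScore()]. The robust standard deviation used by the
#' z-score is an external input supplied by the organizer.
#'
#' @slot label Exercise/sample label.
#' @slot cLab,cRef Laboratory result and assigned value, Bq/l.
#' @slot uLab,uRef Expanded uncertainties (k = 2), Bq/l.
#' @slot sigmaHat Robust standard deviation, Bq/l (`NA` when unpublished;
#'   z is then `NA`).
#' @slot z,deltaX,en z-score (dimensionless), bias (percent), En number.
#'
#' @aliases IntercomparisonScore
#' @seealso [intercomparisonScore()], [evaluatePerformance()]
#' @export
setClass("IntercomparisonScore",
  slots = c(label = "character", cLab = "numeric", cRef = "numeric",
            uLab = "numeric", uRef = "numeric", sigmaHat = "numeric",
            z = "numeric", deltaX = "numeric", en = "numeric"))

setValidity("IntercomparisonScore", function(object) {
  msg <- character(0)
  if (!is.finite(object@cRef) || object@cRef <= 0)
    msg <- c(msg, "'cRef' must be > 0 (Bq/l)")
  if (object@uLab < 0 || object@uRef < 0)
    msg <- c(msg, "expanded uncertainties must be >= 0")
  if (!is.na(object@sigmaHat) && object@sigmaHat <= 0)
    msg <- c(msg, "'sigmaHat' must be > 0 when given")
  if (length(msg)) msg else TRUE
})

setMethod("show", "IntercomparisonScore", function(object) {
  v <- evaluatePerformance(object)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
  cat(sprintf("IntercomparisonScore '%s': C_lab = %.4g +/- %.3g, C_ref = %.4g +/- %.3g Bq/l\n",
              object@label, object@cLab, object@uLab, object@cRef,
              object@uRef))
  cat(sprintf("  z = %s, bias = %s%%, En = %s; satisfactory: z %s, bias %s, En %s\n",
              fmt(object@z), ifelse(is.na(object@deltaX), "NA",
                                    format(roundBias(object@deltaX))),
              fmt(object@en),
              ifelse(is.na(v["z"]), "NA", v["z"]),
              v["bias"], v["en"]))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# SimulationConfig

#' Configuration of the synthetic spectrum / campaign generator
#'
#' Holds the true activity concentration and all counting-condition
#' parameters of a simulated measurement campaign. Defaults reproduce the
#' validation conditions of the implemented urinalysis method: 0.022 Bq/l
#' true concentration, 0.5 l analyzed aliquot, 6-day counts, ~0.049 Bq of
#' tracer, 25 % counting efficiency, tracer recovery 71.4 +/- 7.9 %
#' (truncated to (0, 1]), a reagent blank of ~65 analyte-region counts per
#' 6-day count, and a detector background of a few counts per week in each
#' region.
#'
#' @slot trueC True 210Po activity concentration, Bq/l.
#' @slot aliquotVolume Analyzed aliquot volume, litres.
#' @slot liveTime Live counting time, s.
#' @slot tracerActivity Added tracer activity, Bq.
#' @slot efficiency Detector counting efficiency (fraction in (0, 1]).
#' @slot recoveryMean,recoverySd Mean and SD of the per-sample tracer
#'   recovery draw (truncated normal on (0, 1]).
#' @slot reagentBlankRate Expected reagent-derived 210Po counts per second of
#'   counting under the reference conditions (this configuration's
#'   efficiency and mean recovery).
#' @slot bkgRate210Po,bkgRateTracer Detector background count rates per ROI,
#'   1/s.
#' @slot fwhm Peak full width at half maximum, keV.
#' @slot peakEnergies Named numeric, alpha-line energies `c(tracer=, analyte=)`
#'   in keV.
#' @slot nChannels Number of spectrum channels.
#' @slot slope,intercept Energy calibration of the simulated spectra
#'   (keV/channel, keV).
#' @slot seed Integer seed for the campaign's pseudo-random stream (`NA` to
#'   use the current RNG state).
#'
#' @aliases SimulationConfig
#' @seealso [simulationConfig()], [simulateSpectrum()], [simulateCampaign()]
#' @export
setClass("SimulationConfig",
  slots = c(trueC = "numeric", aliquotVolume = "numeric",
            liveTime = "numeric", tracerActivity = "numeric",
            efficiency = "numeric", recoveryMean = "numeric",
            recoverySd = "numeric", reagentBlankRate = "numeric",
            bkgRate210Po = "numeric", bkgRateTracer = "numeric",
            fwhm = "numeric", peakEnergies = "numeric",
            nChannels = "integer", slope = "numeric", intercept = "numeric",
            seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@trueC < 0) msg <- c(msg, "'trueC' must be >= 0 (Bq/l)")
  if (object@aliquotVolume <= 0) msg <- c(msg, "'aliquotVolume' must be > 0")
  if (object@liveTime <= 0) msg <- c(msg, "'liveTime' must be > 0 (s)")
  if (object@tracerActivity <= 0)
    msg <- c(msg, "'tracerActivity' must be > 0 (Bq)")
  if (object@efficiency <= 0 || object@efficiency > 1)
    msg <- c(msg, "'efficiency' must be in (0, 1]")
  if (object@recoveryMean <= 0 || object@recoveryMean > 1)
    msg <- c(msg, "'recoveryMean' must be in (0, 1]")
  if (object@recoverySd < 0) msg <- c(msg, "'recoverySd' must be >= 0")
  if (object@reagentBlankRate < 0 || object@bkgRate210Po < 0 ||
      object@bkgRateTracer < 0)
    msg <- c(msg, "rates must be >= 0 (1/s)")
  if (object@fwhm <= 0) msg <- c(msg, "'fwhm' must be > 0 (keV)")
  if (length(object@peakEnergies) != 2L ||
      !all(c("tracer", "analyte") %in% names(object@peakEnergies)))
    msg <- c(msg, "'peakEnergies' must be named c(tracer=, analyte=)")
  if (object@nChannels < 2L) msg <- c(msg, "'nChannels' must be >= 2")
  if (object@slope <= 0) msg <- c(msg, "'slope' must be > 0 (keV/channel)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: true C = %.4g Bq/l, V = %.3g l, ",
                     "t = %.6g s, A_tr = %.4g Bq\n"),
              object@trueC, object@aliquotVolume, object@liveTime,
              object@tracerActivity))
  cat(sprintf("  E = %.2f, recovery %.3f +/- %.3f, reagent blank %.3g counts/s (ref)\n",
              object@efficiency, object@recoveryMean, object@recoverySd,
              object@reagentBlankRate))
  cat(sprintf("  peaks %.1f / %.1f keV, FWHM %.1f keV, %d channels at %.3g keV/ch\n",
              object@peakEnergies["tracer"], object@peakEnergies["analyte"],
              object@fwhm, object@nChannels, object@slope))
  invisible(NULL)
})
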