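#' Accessors for AlphaSpectrum and EnergyCalibration objects
#'
#' Slot accessors: `counts()` returns the integer channel counts,
#' `liveTime()` the live counting time in seconds, `detectorId()` the
#' detector label, `nChannels()` the number of channels, `calibration()`
#' the attached [EnergyCalibration-class] (or `NULL`), and
#' `channelEnergies()` the channel-center energies in keV (errors on an
#' uncalibrated spectrum).
#'
#' @param object An [AlphaSpectrum-class] object.
#' @param value An [EnergyCalibration-class] (or `NULL`) for the replacement
#'   method.
#' @return See description; `calibration<-` returns the modified spectrum.
#' @examples
#' sp <- alphaSpectrum(c(1, 2, 3), liveTime = 60)
#' counts(sp)
#' calibration(sp) <- energyCalibration(10, 3000)
#' channelEnergies(sp)
#' @name spectrum-accessors
#' @aliases counts liveTime detectorId nChannels calibration calibration<-
#'   channelEnergies
NULL

#' @rdname spectrum-accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname spectrum-accessors
#' @export
setMethod("counts", "AlphaSpectrum", function(object) object@counts)

#' @rdname spectrum-accessors
#' @export
setGeneric("liveTime", function(object) standardGeneric("liveTime"))

#' @rdname spectrum-accessors
#' @export
setMethod("liveTime", "AlphaSpectrum", function(object) object@liveTime)

#' @rdname spectrum-accessors
#' @export
setGeneric("detectorId", function(object) standardGeneric("detectorId"))

#' @rdname spectrum-accessors
#' @export
setMethod("detectorId", "AlphaSpectrum", function(object) object@detectorId)

#' @rdname spectrum-accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname spectrum-accessors
#' @export
setMethod("nChannels", "AlphaSpectrum",
          function(object) length(object@counts))

#' @rdname spectrum-accessors
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))

#' @rdname spectrum-accessors
#' @export
setMethod("calibration", "AlphaSpectrum", function(object) object@calibration)

#' @rdname spectrum-accessors
#' @export
setGeneric("calibration<-",
           function(object, value) standardGeneric("calibration<-"))

#' @rdname spectrum-accessors
#' @export
setMethod("calibration<-", "AlphaSpectrum", function(object, value) {
  object@calibration <- value
  validObject(object)
  object
})

#' @rdname spectrum-accessors
#' @export
setGeneric("channelEnergies",
           function(object) standardGeneric("channelEnergies"))

#' @rdname spectrum-accessors
#' @export
setMethod("channelEnergies", "AlphaSpectrum", function(object) {
  cal <- object@calibration
  if (is.null(cal))
    stop("spectrum is not energy-calibrated", call. = FALSE)
  cal@intercept + cal@slope * (seq_along(object@counts) - 1)
})

#' Extract a peak summary as a plain list
#'
#' @param summary A [PeakSummary-class] object.
#' @return A named list with `label`, `grossCounts`, `centroid`, `fwhm`.
#' @examples
#' sp <- alphaSpectrum(c(0, 5, 10, 5, 0), 3600,
#'                     calibration = energyCalibration(10, 0))
#' peakAsList(integrateROI(sp, roi("demo", 0, 50)))
#' @export
peakAsList <- function(summary) {
  stopifnot(is(summary, "PeakSummary"))
  list(label = summary@label, grossCounts = summary@grossCounts,
       centroid = summary@centroid, fwhm = summary@fwhm)
}
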