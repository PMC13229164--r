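# Spectrum I/O, energy calibration and ROI summarization.
#
# SPE dialect supported (IAEA ASCII): $SPEC_ID, $MEAS_TIM (live and real
# time, seconds), $DATA (first last, then counts one per line), optional
# $ENER_FIT (intercept slope) and $DATE_MEA. Two-column dialect:
# channel <TAB> count with a "# live_time_s=" header comment.

.speBlocks <- function(lines) {
  starts <- grep("^\\$[A-Z_]+:", lines)
  if (!length(starts)) stop("no $-blocks found: not an SPE file",
                            call. = FALSE)
  names <- sub("^\\$([A-Z_]+):.*$", "\\1", lines[starts])
  ends <- c(starts[-1] - 1L, length(lines))
  blocks <- Map(function(s, e) {
    if (e < s + 1L) character(0) else lines[(s + 1L):e]
  }, starts, ends)
  names(blocks) <- names
  attr(blocks, "starts") <- stats::setNames(starts, names)
  blocks
}

.parseCountLine <- function(text, lineNo) {
  tok <- strsplit(trimws(text), "\\s+")[[1]]
  val <- suppressWarnings(as.numeric(tok))
  if (anyNA(val) || !all(.isWholeNumber(val)) || any(val < 0))
    stop(sprintf("line %d: expected non-negative integer count, got '%s'",
                 lineNo, text), call. = FALSE)
  val
}

#' Read an alpha spectrum from disk
#'
#' Parses either the IAEA SPE ASCII dialect (`$MEAS_TIM`, `$DATA`, optional
#' `$ENER_FIT`, `$SPEC_ID`, `$DATE_MEA` blocks) or plain two-column
#' `channel<TAB>count` text with the live time in a `# live_time_s=` header
#' comment. Malformed blocks, non-integer counts and a missing live time
#' raise errors naming the offending line.
#'
#' @param path Path to the spectrum file.
#' @param dialect `"spe"` or `"two_column"`.
#' @return An [AlphaSpectrum-class] object (calibrated when the file carries
#'   an energy fit).
#' @seealso [writeSpectrum()]
#' @examples
#' f <- tempfile(fileext = ".spe")
#' writeSpectrum(alphaSpectrum(c(1, 2, 3, 4), 600), f)
#' readSpectrum(f)
#' @export
readSpectrum <- function(path, dialect = c("spe", "two_column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "spe") .readSpe(lines, path) else .readTwoColumn(lines, path)
}

.readSpe <- function(lines, path) {
  blocks <- .speBlocks(lines)
  starts <- attr(blocks, "starts")
  if (!"MEAS_TIM" %in% names(blocks) || !length(blocks$MEAS_TIM))
    stop("missing $MEAS_TIM block (live time) in ", path, call. = FALSE)
  tim <- suppressWarnings(as.numeric(
    strsplit(trimws(blocks$MEAS_TIM[1]), "\\s+")[[1]]))
  if (!length(tim) || is.na(tim[1]) || tim[1] <= 0)
    stop(sprintf("line %d: cannot parse live time from $MEAS_TIM",
                 starts["MEAS_TIM"] + 1L), call. = FALSE)
  if (!"DATA" %in% names(blocks))
    stop("missing $DATA block in ", path, call. = FALSE)
  dat <- blocks$DATA
  dat <- dat[nzchar(trimws(dat))]
  if (length(dat) < 2L)
    stop(sprintf("line %d: empty or truncated $DATA block",
                 starts["DATA"]), call. = FALSE)
  range <- suppressWarnings(as.numeric(strsplit(trimws(dat[1]), "\\s+")[[1]]))
  if (length(range) != 2L || anyNA(range) || !all(.isWholeNumber(range)) ||
      range[2] < range[1])
    stop(sprintf("line %d: expected '$DATA first last' channel range",
                 starts["DATA"] + 1L), call. = FALSE)
  nWant <- range[2] - range[1] + 1
  cnt <- unlist(Map(.parseCountLine, dat[-1],
                    starts["DATA"] + seq_along(dat[-1]) + 1L),
                use.names = FALSE)
  if (length(cnt) != nWant)
    stop(sprintf("$DATA declares %d channels but %d counts were read in %s",
                 nWant, length(cnt), path), call. = FALSE)
  cal <- NULL
  if ("ENER_FIT" %in% names(blocks) && length(blocks$ENER_FIT)) {
    ef <- suppressWarnings(as.numeric(
      strsplit(trimws(blocks$ENER_FIT[1]), "\\s+")[[1]]))
    if (length(ef) >= 2L && !anyNA(ef[1:2]) && ef[2] > 0)
      cal <- energyCalibration(slope = ef[2], intercept = ef[1])
  }
  id <- if ("SPEC_ID" %in% names(blocks) && length(blocks$SPEC_ID))
    trimws(blocks$SPEC_ID[1]) else ""
  acq <- if ("DATE_MEA" %in% names(blocks) && length(blocks$DATE_MEA))
    trimws(blocks$DATE_MEA[1]) else NA_character_
  alphaSpectrum(cnt, liveTime = tim[1], detectorId = id,
                acquisitionStart = acq, calibration = cal)
}

.readTwoColumn <- function(lines, path) {
  headers <- grep("^#", lines, value = TRUE)
  lt <- grep("live_time_s\\s*=", headers, value = TRUE)
  if (!length(lt))
    stop("missing '# live_time_s=' header in ", path, call. = FALSE)
  liveTime <- suppressWarnings(as.numeric(sub(".*live_time_s\\s*=\\s*", "",
                                              lt[1])))
  if (is.na(liveTime) || liveTime <= 0)
    stop("cannot parse live time from header of ", path, call. = FALSE)
  id <- grep("detector_id\\s*=", headers, value = TRUE)
  det <- if (length(id)) trimws(sub(".*detector_id\\s*=\\s*", "", id[1]))
         else ""
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  ch <- cnt <- numeric(length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(lines[body[i]]), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 2L || anyNA(val) || !all(.isWholeNumber(val)) ||
        val[2] < 0)
      stop(sprintf("line %d: expected 'channel<TAB>count', got '%s'",
                   body[i], lines[body[i]]), call. = FALSE)
    ch[i] <- val[1]; cnt[i] <- val[2]
  }
  o <- order(ch)
  ch <- ch[o]; cnt <- cnt[o]
  if (any(diff(ch) != 1))
    stop("channel numbers must be consecutive in ", path, call. = FALSE)
  alphaSpectrum(cnt, liveTime = liveTime, detectorId = det)
}

#' Write an alpha spectrum to disk
#'
#' Inverse of [readSpectrum()]; the write/read round trip preserves counts
#' and live time exactly (and the energy fit in the SPE dialect).
#'
#' @param spectrum An [AlphaSpectrum-class] object.
#' @param path Output path.
#' @param dialect `"spe"` or `"two_column"`.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path, dialect = c("spe", "two_column")) {
  dialect <- match.arg(dialect)
  stopifnot(is(spectrum, "AlphaSpectrum"))
  n <- length(spectrum@counts)
  if (dialect == "spe") {
    out <- c("$SPEC_ID:", spectrum@detectorId)
    if (!is.na(spectrum@acquisitionStart))
      out <- c(out, "$DATE_MEA:", spectrum@acquisitionStart)
    out <- c(out, "$MEAS_TIM:",
             sprintf("%s %s", format(spectrum@liveTime),
                     format(spectrum@liveTime)),
             "$DATA:", sprintf("0 %d", n - 1L),
             format(spectrum@counts))
    if (!is.null(spectrum@calibration))
      out <- c(out, "$ENER_FIT:",
               sprintf("%.10g %.10g", spectrum@calibration@intercept,
                       spectrum@calibration@slope))
  } else {
    out <- c(sprintf("# live_time_s=%s", format(spectrum@liveTime)),
             if (nzchar(spectrum@detectorId))
               sprintf("# detector_id=%s", spectrum@detectorId),
             sprintf("%d\t%d", 0:(n - 1L), spectrum@counts))
  }
  writeLines(out, path)
  invisible(path)
}

#' Fit a linear energy calibration from identified peaks
#'
#' Least-squares straight line through (channel, known energy) pairs of a
#' multi-line calibration source, e.g. the four alpha lines of
#' 238U/234U/239Pu/241Am; any source with at least two lines at distinct
#' channels is accepted.
#'
#' @param channels Channel positions of the identified peaks (0-based
#'   centroids; >= 2 distinct values).
#' @param energies Known alpha energies, keV (same length).
#' @return An [EnergyCalibration-class] with fit residuals (keV).
#' @examples
#' calibrateEnergy(c(100, 200), c(4000, 5000))  # slope 10, intercept 3000
#' @export
calibrateEnergy <- function(channels, energies) {
  channels <- as.numeric(channels); energies <- as.numeric(energies)
  if (length(channels) != length(energies))
    stop("'channels' and 'energies' must have equal length", call. = FALSE)
  if (length(unique(channels)) < 2L)
    stop("need at least 2 peaks at distinct channels", call. = FALSE)
  fit <- stats::lm(energies ~ channels)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be > 0 (energies not increasing with channel)",
         call. = FALSE)
  energyCalibration(slope = slope,
                    intercept = unname(stats::coef(fit)[1]),
                    residuals = unname(stats::residuals(fit)))
}

#' Default tracer/analyte regions of interest
#'
#' Energy windows around the nominal 209Po (tracer) and 210Po (analyte)
#' alpha lines, spanning `-lowOffset`/`+highOffset` keV around each line.
#' The asymmetry (default 60 keV below, 40 keV above) catches the
#' low-energy tailing typical of alpha sources while keeping the two
#' windows disjoint.
#'
#' @param lines Named numeric `c(tracer=, analyte=)` line energies in keV;
#'   defaults to [poAlphaLines()].
#' @param lowOffset,highOffset Window extent below/above each line, keV.
#' @return Named list of two [RegionOfInterest-class] objects (`tracer`,
#'   `analyte`).
#' @examples
#' defaultROIs()
#' @export
defaultROIs <- function(lines = poAlphaLines(), lowOffset = 60,
                        highOffset = 40) {
  .checkScalar(lowOffset, "lowOffset", positive = TRUE)
  .checkScalar(highOffset, "highOffset", positive = TRUE)
  out <- list(
    tracer = roi("tracer", lines[["tracer"]] - lowOffset,
                 lines[["tracer"]] + highOffset),
    analyte = roi("analyte", lines[["analyte"]] - lowOffset,
                  lines[["analyte"]] + highOffset))
  if (out$tracer@eHigh > out$analyte@eLow &&
      out$analyte@eHigh > out$tracer@eLow)
    stop("tracer and analyte ROIs overlap; narrow the offsets",
         call. = FALSE)
  out
}

#' Integrate an energy region of interest
#'
#' Sums the counts of all channels whose center energy falls in the
#' half-open window `[eLow, eHigh)` and reports the count-weighted centroid
#' and the FWHM obtained by linear interpolation at half the modal-bin
#' height (no peak-shape fitting). Centroid and FWHM are `NA` for an empty
#' window or when a half-maximum crossing lies outside it.
#'
#' @param spectrum A calibrated [AlphaSpectrum-class].
#' @param roi A [RegionOfInterest-class].
#' @return A [PeakSummary-class] object.
#' @examples
#' sp <- alphaSpectrum(c(0, 5, 10, 5, 0), 3600,
#'                     calibration = energyCalibration(10, 0))
#' integrateROI(sp, roi("demo", 0, 50))
#' @export
integrateROI <- function(spectrum, roi) {
  stopifnot(is(spectrum, "AlphaSpectrum"), is(roi, "RegionOfInterest"))
  e <- channelEnergies(spectrum)   # errors when uncalibrated
  if (roi@eHigh <= e[1] || roi@eLow > e[length(e)])
    stop(sprintf("ROI '%s' [%.6g, %.6g) lies outside the spectrum energy range [%.6g, %.6g]",
                 roi@label, roi@eLow, roi@eHigh, e[1], e[length(e)]),
         call. = FALSE)
  sel <- which(e >= roi@eLow & e < roi@eHigh)
  cnt <- as.numeric(spectrum@counts[sel])
  gross <- sum(cnt)
  if (gross == 0)
    return(new("PeakSummary", label = roi@label, grossCounts = 0,
               centroid = NA_real_, fwhm = NA_real_))
  centroid <- sum(cnt * e[sel]) / gross
  fwhm <- .fwhmInterp(e[sel], cnt)
  new("PeakSummary", label = roi@label, grossCounts = gross,
      centroid = centroid, fwhm = fwhm)
}

# linear interpolation at half maximum of the modal bin; NA when a crossing
# is not bracketed inside the window
.fwhmInterp <- function(e, cnt) {
  m <- which.max(cnt)
  half <- cnt[m] / 2
  eLeft <- eRight <- NA_real_
  if (m > 1L) {
    for (i in seq(m - 1L, 1L)) {
      if (cnt[i] < half && cnt[i + 1L] >= half) {
        eLeft <- e[i] + (half - cnt[i]) / (cnt[i + 1L] - cnt[i]) *
          (e[i + 1L] - e[i])
        break
      }
    }
  }
  if (m < length(cnt)) {
    for (i in seq(m + 1L, length(cnt))) {
      if (cnt[i] < half && cnt[i - 1L] >= half) {
        eRight <- e[i - 1L] + (cnt[i - 1L] - half) / (cnt[i - 1L] - cnt[i]) *
          (e[i] - e[i - 1L])
        break
      }
    }
  }
  if (is.na(eLeft) || is.na(eRight)) return(NA_real_)
  out <- eRight - eLeft
  if (out <= 0) NA_real_ else out
}

#' Detector counting efficiency from a certified calibration source
#'
#' `E = counts / (liveTime * certifiedActivity)`, the fraction of emitted
#' alpha particles registered by the detector. Values above 0.5 are
#' physically implausible for a 2-pi counting geometry and trigger a
#' warning, as does a zero-count measurement.
#'
#' @param counts Gross counts of the calibration peak (>= 0).
#' @param liveTime Live counting time, s (> 0).
#' @param certifiedActivity Certified source activity, Bq (> 0).
#' @return Counting efficiency (fraction).
#' @examples
#' countingEfficiency(8640, 86400, 0.4)  # 0.25
#' @export
countingEfficiency <- function(counts, liveTime, certifiedActivity) {
  .checkScalar(counts, "counts", nonneg = TRUE)
  .checkScalar(liveTime, "liveTime", positive = TRUE)
  .checkScalar(certifiedActivity, "certifiedActivity", positive = TRUE)
  e <- counts / (liveTime * certifiedActivity)
  if (counts == 0)
    warning("zero counts: efficiency is 0; check the measurement",
            call. = FALSE)
  if (e > 0.5)
    warning(sprintf("efficiency %.3g exceeds 0.5, implausible for 2-pi geometry",
                    e), call. = FALSE)
  e
}
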