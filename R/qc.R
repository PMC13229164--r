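# Method-performance statistics: repeatability CV, proficiency-test scores
# and spectrometer stability charting.

#' Repeatability of a measurement series
#'
#' Percentage coefficient of variation `CV = SD / mean * 100` of repeated
#' activity-concentration determinations on aliquots of the same sample,
#' with the sample (n - 1) standard deviation.
#'
#' @aliases PrecisionSeries
#' @slot values The individual concentrations C_i, Bq/l.
#' @slot mean,sd Mean and sample SD, Bq/l.
#' @slot cv Coefficient of variation, percent.
#' @export
setClass("PrecisionSeries",
  slots = c(values = "numeric", mean = "numeric", sd = "numeric",
            cv = "numeric"))

setMethod("show", "PrecisionSeries", function(object) {
  cat(sprintf("PrecisionSeries (n = %d): mean %.4f Bq/l, SD %.4f Bq/l, CV %.1f%%\n",
              length(object@values), object@mean, object@sd, object@cv))
  invisible(NULL)
})

#' @describeIn PrecisionSeries-class Compute the precision summary from a
#'   vector of repeated concentrations (n >= 2, positive mean).
#' @param values Numeric vector of concentrations, Bq/l.
#' @return A `PrecisionSeries` object.
#' @examples
#' cvPrecision(c(1, 2, 3))  # mean 2, SD 1, CV 50 %
#' @export
cvPrecision <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean concentration must be > 0", call. = FALSE)
  s <- stats::sd(values)
  new("PrecisionSeries", values = values, mean = m, sd = s,
      cv = s / m * 100)
}

#' Proficiency-test statistics
#'
#' `zScore(cLab, cRef, sigmaHat)` gives
#' `z = (C_lab - C_ref) / sigmaHat` with the organizer's robust standard
#' deviation; `biasPercent(cLab, cRef)` the relative bias
#' `(C_lab - C_ref) / C_ref * 100`; and
#' `enNumber(cLab, cRef, uLab, uRef)` the En number
#' `(C_lab - C_ref) / sqrt(U_lab^2 + U_ref^2)` weighting the deviation by
#' both expanded (k = 2) uncertainties.
#'
#' @param cLab Laboratory result, Bq/l.
#' @param cRef Assigned value, Bq/l (> 0 for the bias).
#' @param sigmaHat Robust standard deviation, Bq/l (> 0); an external input
#'   supplied by the organizer, never computed here.
#' @param uLab,uRef Expanded uncertainties (k = 2), Bq/l, not both zero.
#' @return The statistic (z and En dimensionless, bias in percent).
#' @examples
#' zScore(0.5, 0.4, 0.05)            # 2
#' biasPercent(0.475, 0.490)          # -3.06...
#' enNumber(0.475, 0.490, 0.12, 0.023)
#' @name pt-scores
NULL

#' @rdname pt-scores
#' @export
zScore <- function(cLab, cRef, sigmaHat) {
  .checkScalar(cLab, "cLab"); .checkScalar(cRef, "cRef")
  .checkScalar(sigmaHat, "sigmaHat", positive = TRUE)
  (cLab - cRef) / sigmaHat
}

#' @rdname pt-scores
#' @export
biasPercent <- function(cLab, cRef) {
  .checkScalar(cLab, "cLab")
  .checkScalar(cRef, "cRef", positive = TRUE)
  (cLab - cRef) / cRef * 100
}

#' @rdname pt-scores
#' @export
enNumber <- function(cLab, cRef, uLab, uRef) {
  .checkScalar(cLab, "cLab"); .checkScalar(cRef, "cRef")
  .checkScalar(uLab, "uLab", nonneg = TRUE)
  .checkScalar(uRef, "uRef", nonneg = TRUE)
  if (uLab == 0 && uRef == 0)
    stop("both expanded uncertainties are zero", call. = FALSE)
  (cLab - cRef) / sqrt(uLab^2 + uRef^2)
}

#' Build an intercomparison score from reported quantities
#'
#' Computes z (when the robust SD is supplied), bias and En for one
#' proficiency-test sample and stores them with their inputs.
#'
#' @param cLab,cRef Laboratory result and assigned value, Bq/l.
#' @param uLab,uRef Expanded uncertainties (k = 2), Bq/l.
#' @param sigmaHat Robust standard deviation, Bq/l (`NA` when unpublished).
#' @param label Exercise label.
#' @return An [IntercomparisonScore-class] object.
#' @examples
#' intercomparisonScore(0.475, 0.490, 0.12, 0.023, label = "20POA")
#' @export
intercomparisonScore <- function(cLab, cRef, uLab, uRef,
                                 sigmaHat = NA_real_, label = "") {
  z <- if (is.na(sigmaHat)) NA_real_ else zScore(cLab, cRef, sigmaHat)
  new("IntercomparisonScore", label = as.character(label),
      cLab = as.numeric(cLab), cRef = as.numeric(cRef),
      uLab = as.numeric(uLab), uRef = as.numeric(uRef),
      sigmaHat = as.numeric(sigmaHat), z = z,
      deltaX = biasPercent(cLab, cRef),
      en = enNumber(cLab, cRef, uLab, uRef))
}

#' Apply the proficiency-test acceptance criteria
#'
#' Satisfactory iff `|z| < 2`, `-25 % < bias < 50 %` and `|En| < 1`; all
#' strict inequalities, the z and En criteria applied to magnitudes (a
#' negative score of small magnitude passes). `z` is `NA` when the robust
#' SD was not supplied.
#'
#' @param score An [IntercomparisonScore-class], or a named list/vector
#'   with elements `z`, `deltaX`, `en`.
#' @return Named logical vector `c(z=, bias=, en=)`.
#' @examples
#' s <- intercomparisonScore(0.475, 0.490, 0.12, 0.023)
#' evaluatePerformance(s)
#' @export
evaluatePerformance <- function(score) {
  if (is(score, "IntercomparisonScore")) {
    z <- score@z; dx <- score@deltaX; en <- score@en
  } else {
    z <- score[["z"]]; dx <- score[["deltaX"]]; en <- score[["en"]]
  }
  c(z = if (is.na(z)) NA else abs(z) < 2,
    bias = dx > -25 && dx < 50,
    en = abs(en) < 1)
}

#' Shewhart-style stability chart for spectrometer QC measurements
#'
#' From the periodic measurements of the calibration source in each
#' chamber, establishes per-detector control limits `mean +/- nSigma * SD`
#' for the peak area, centroid and FWHM using the first `m` records
#' (default: all but the most recent), and flags every record falling
#' outside its limits.
#'
#' @param history `data.frame` with columns `date`, `detectorId`,
#'   `peakArea`, `centroid`, `fwhm`; at least 2 records per detector.
#' @param m Number of leading records (per detector, in date order) that
#'   define the limits; `NULL` means all but the last.
#' @param nSigma Width of the control limits in standard deviations.
#' @return The history with logical columns `flagArea`, `flagCentroid`,
#'   `flagFwhm` appended and the per-detector limits as the `"limits"`
#'   attribute.
#' @examples
#' h <- data.frame(date = as.Date("2024-01-01") + 0:5, detectorId = "D1",
#'                 peakArea = 1000, centroid = 5150, fwhm = 18)
#' stabilityChart(h)
#' @export
stabilityChart <- function(history, m = NULL, nSigma = 3) {
  need <- c("date", "detectorId", "peakArea", "centroid", "fwhm")
  if (!is.data.frame(history) || !all(need %in% names(history)))
    stop("'history' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  .checkScalar(nSigma, "nSigma", positive = TRUE)
  metrics <- c("peakArea", "centroid", "fwhm")
  history <- history[order(history$detectorId, history$date), , drop = FALSE]
  out <- history
  for (f in c("flagArea", "flagCentroid", "flagFwhm")) out[[f]] <- NA
  limits <- list()
  for (det in unique(history$detectorId)) {
    idx <- which(history$detectorId == det)
    n <- length(idx)
    if (n < 2L)
      stop(sprintf("detector '%s': need at least 2 records", det),
           call. = FALSE)
    mDet <- if (is.null(m)) n - 1L else min(m, n)
    if (mDet < 2L)
      stop("need at least 2 baseline records to set limits", call. = FALSE)
    base <- history[idx[seq_len(mDet)], , drop = FALSE]
    lim <- lapply(metrics, function(v) {
      mu <- mean(base[[v]]); s <- stats::sd(base[[v]])
      c(center = mu, lower = mu - nSigma * s, upper = mu + nSigma * s)
    })
    names(lim) <- metrics
    limits[[det]] <- lim
    for (k in seq_along(metrics)) {
      v <- history[idx, metrics[k]]
      flag <- v < lim[[k]]["lower"] | v > lim[[k]]["upper"]
      out[idx, c("flagArea", "flagCentroid", "flagFwhm")[k]] <- flag
    }
  }
  attr(out, "limits") <- limits
  out
}
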