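# Core calculation chain: tracer recovery, reagent-blank constant K,
# blank-equivalent counts N', activity concentration C_lab, Currie-type MDC
# and the uncertainty budget.
#
# Quantities, for a record r:
#   netTracer  = N_tr - B_tr * t      (must be > 0 for any computation)
#   N'         = K * netTracer / A_tr (reagent 210Po normalized to the
#                                      sample's counting conditions)
#   C_lab      = (N_210Po - N' - B_210Po * t) * A_tr / (netTracer * V)

.netTracer <- function(x) {
  net <- x@countsTracer - x@bkgRateTracer * x@liveTime
  if (net <= 0)
    stop(sprintf("net tracer counts must be > 0 (got %.4g) for '%s'",
                 net, if (is(x, "MeasurementRecord")) x@sampleId else
                   x@blankId), call. = FALSE)
  net
}

.asK <- function(K) {
  if (is(K, "KConstant")) return(K)
  .checkScalar(K, "K", nonneg = TRUE)
  kConstant(K, uKRel = 0, nBlanks = 1L)
}

#' Tracer recovery (chemical yield)
#'
#' `R = N_tr / (t * E * A_tr)`: the fraction of the added 209Po tracer that
#' survived the radiochemistry and deposition, judged from its peak counts.
#' Gross tracer counts are used by default; `netCounts = TRUE` substitutes
#' `N_tr - B_tr * t`. Recovery is a quality-control quantity only — it
#' cancels out of the activity-concentration equation.
#'
#' @param record A [MeasurementRecord-class] with a known `efficiency`.
#' @param netCounts Use background-subtracted tracer counts instead of gross.
#' @return Recovery as a fraction.
#' @examples
#' r <- measurementRecord(500, 6048, 345600, 0.1, 0.5, efficiency = 0.25)
#' tracerRecovery(r)  # 0.70
#' @export
tracerRecovery <- function(record, netCounts = FALSE) {
  stopifnot(is(record, "MeasurementRecord"))
  if (is.na(record@efficiency))
    stop("counting efficiency is required for tracer recovery", call. = FALSE)
  n <- if (netCounts)
    record@countsTracer - record@bkgRateTracer * record@liveTime
  else record@countsTracer
  n / (record@liveTime * record@efficiency * record@tracerActivity)
}

#' Per-blank reagent constant
#'
#' For one full-procedure blank,
#' `K_i = (N_210Po,blank -/+ B_210Po * t) * A_tr,blank / (N_tr,blank - B_tr * t)`.
#' The default `"net"` mode subtracts the detector background from the
#' blank's analyte counts (clamped at zero), so that K captures only the
#' reagent-derived 210Po; `"as_printed"` adds it, preserving the typeset
#' formula. See the package vignette for why net mode is the default.
#'
#' @param blank A [BlankMeasurement-class].
#' @param mode `"net"` (default) or `"as_printed"`.
#' @return K_i in Bq.
#' @examples
#' b <- blankMeasurement(70, 4000, 0.05, 518400,
#'                       bkgRate210Po = 3 / 518400, bkgRateTracer = 3 / 518400)
#' kSingle(b)                      # 67 * 0.05 / 3997
#' kSingle(b, mode = "as_printed") # 73 * 0.05 / 3997
#' @export
kSingle <- function(blank, mode = c("net", "as_printed")) {
  stopifnot(is(blank, "BlankMeasurement"))
  mode <- match.arg(mode)
  denom <- .netTracer(blank)
  bt <- blank@bkgRate210Po * blank@liveTime
  num <- if (mode == "net") max(blank@counts210Po - bt, 0)
         else blank@counts210Po + bt
  num * blank@tracerActivity / denom
}

#' Aggregate a blank series into the K constant
#'
#' K is the arithmetic mean (or, optionally, median) of the per-blank
#' constants [kSingle()]; its relative standard uncertainty is the standard
#' error of that mean, `sd(K_i) / (K * sqrt(n))`, for `n >= 2`. With a
#' single blank no spread is observable and `uKRelDefault` is assigned.
#'
#' @param blanks A list of [BlankMeasurement-class] objects (>= 1).
#' @param mode Passed to [kSingle()].
#' @param aggregate `"mean"` (default) or `"median"`.
#' @param uKRelDefault Relative uncertainty assigned when `n = 1` or `K = 0`.
#' @return A [KConstant-class] object.
#' @examples
#' b <- blankMeasurement(70, 4000, 0.05, 518400)
#' kAggregate(list(b, b))
#' @export
kAggregate <- function(blanks, mode = c("net", "as_printed"),
                       aggregate = c("mean", "median"),
                       uKRelDefault = 0.3) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  if (!is.list(blanks) || !length(blanks))
    stop("need a non-empty list of blank measurements", call. = FALSE)
  .checkScalar(uKRelDefault, "uKRelDefault", nonneg = TRUE)
  ki <- vapply(blanks, kSingle, numeric(1), mode = mode)
  K <- if (aggregate == "mean") mean(ki) else stats::median(ki)
  n <- length(ki)
  uRel <- if (n >= 2L && K > 0) stats::sd(ki) / (K * sqrt(n))
          else uKRelDefault
  kConstant(K, uKRel = uRel, nBlanks = n, mode = mode)
}

#' Blank-equivalent counts for an analytical sample
#'
#' `N' = K * (N_tr - B_tr * t) / A_tr`: the reagent-derived 210Po counts
#' expected under the sample's own counting conditions (time, recovery and
#' efficiency enter through the sample's net tracer counts, so no separate
#' normalization is needed).
#'
#' @param K A [KConstant-class] or a bare K value in Bq.
#' @param record A [MeasurementRecord-class].
#' @return Blank-equivalent counts N'.
#' @examples
#' r <- measurementRecord(500, 4000, 518400, 0.05, 0.5,
#'                        bkgRateTracer = 3 / 518400)
#' blankEquivalentCounts(8.381e-4, r)
#' @export
blankEquivalentCounts <- function(K, record) {
  stopifnot(is(record, "MeasurementRecord"))
  K <- .asK(K)
  K@K * .netTracer(record) / record@tracerActivity
}

# decay-correction factor: back-decay from count start to collection plus
# the average-decay-during-counting factor lambda*t / (1 - exp(-lambda*t))
.decayFactor <- function(delayDays, liveTimeSeconds) {
  lam <- po210DecayConstantPerDay()
  tDays <- liveTimeSeconds / 86400
  exp(lam * delayDays) * lam * tDays / (1 - exp(-lam * tDays))
}

#' Activity concentration of 210Po in a sample
#'
#' `C_lab = (N_210Po - N' - B_210Po * t) * A_tr / ((N_tr - B_tr * t) * V)`,
#' the tracer-normalized, reagent-blank- and background-corrected activity
#' concentration in Bq per litre of the analyzed aliquot's parent sample.
#' Counting efficiency and recovery cancel between the two ROIs and never
#' appear. A negative result is reported as-is (it is flagged below the MDC
#' downstream); clamping would bias blank-level quality-control statistics.
#'
#' With `decayCorrect = TRUE` the result is corrected for 210Po decay
#' (half-life 138.4 d) between sample collection and counting
#' (`delayDays`) and for decay during the count itself.
#'
#' @param record A [MeasurementRecord-class].
#' @param K A [KConstant-class] (or bare Bq value) from the blank series.
#' @param decayCorrect Apply the decay correction (default off).
#' @param delayDays Days from sample collection to the start of counting
#'   (used only when `decayCorrect = TRUE`).
#' @return C_lab in Bq/l.
#' @examples
#' r <- measurementRecord(500, 4000, 345600, 0.05, 0.5,
#'                        bkgRate210Po = 1e-5, bkgRateTracer = 1e-5)
#' activityConcentration(r, K = 0)
#' @export
activityConcentration <- function(record, K, decayCorrect = FALSE,
                                  delayDays = 0) {
  stopifnot(is(record, "MeasurementRecord"))
  net <- .netTracer(record)
  nprime <- blankEquivalentCounts(K, record)
  C <- (record@counts210Po - nprime -
          record@bkgRate210Po * record@liveTime) *
    record@tracerActivity / (net * record@aliquotVolume)
  if (decayCorrect) {
    .checkScalar(delayDays, "delayDays", nonneg = TRUE)
    C <- C * .decayFactor(delayDays, record@liveTime)
  }
  C
}

#' Minimum detectable activity concentration
#'
#' Currie-type detection limit scaled to concentration units by the tracer
#' normalization and aliquot volume. The default `"currie_sqrt"` form is
#' \deqn{MDC = (4.66 \sqrt{N' + B_{210Po} t} + 3) \, A_{tr} /
#'       (V (N_{tr} - B_{tr} t))}{MDC = (4.66*sqrt(N' + B*t) + 3) * A_tr /
#'       (V * (N_tr - B_tr*t))}
#' i.e. 4.66 standard deviations of the blank counts plus a small-count
#' constant. The `"as_printed"` variant omits the radical and multiplies
#' 4.66 by the blank counts themselves; it is dimensionally inconsistent
#' and several-fold too high, and is retained only for auditability (see
#' the vignette). Setting `includeReagentBlank = FALSE` drops N', giving
#' the blank-style MDC that reflects the detector background alone.
#'
#' @param record A [MeasurementRecord-class].
#' @param K A [KConstant-class] or bare Bq value.
#' @param formula `"currie_sqrt"` (default) or `"as_printed"`.
#' @param includeReagentBlank Include the reagent blank-equivalent counts
#'   N' (default) or eliminate them.
#' @return MDC in Bq/l.
#' @examples
#' r <- measurementRecord(500, 4000, 518400, 0.05, 0.5)
#' mdc(r, K = 8.381e-4)
#' @export
mdc <- function(record, K, formula = c("currie_sqrt", "as_printed"),
                includeReagentBlank = TRUE) {
  stopifnot(is(record, "MeasurementRecord"))
  formula <- match.arg(formula)
  net <- .netTracer(record)
  nprime <- if (includeReagentBlank) blankEquivalentCounts(K, record) else 0
  blankCounts <- nprime + record@bkgRate210Po * record@liveTime
  term <- if (formula == "currie_sqrt") 4.66 * sqrt(blankCounts) + 3
          else 4.66 * blankCounts + 3
  term * record@tracerActivity / (record@aliquotVolume * net)
}

#' Relative uncertainty budget of an activity determination
#'
#' The components entering the combined relative uncertainty of C_lab:
#' Poisson counting uncertainties of the analyte and tracer peaks (gross
#' counts over net counts), the reagent-blank contribution (the K
#' constant's relative uncertainty propagated through N'), and the
#' certificate/weighing uncertainties of the tracer activity and of the
#' tracer solution mass. The counting components are undefined (`NA`) when
#' the net analyte signal is non-positive.
#'
#' @param record A [MeasurementRecord-class].
#' @param K A [KConstant-class] or bare Bq value.
#' @param relTracerActivity Relative standard uncertainty of the tracer
#'   specific activity; default 0.0050/2/0.4891 from the certificate value
#'   0.4891 +/- 0.0050 Bq/g (k = 2).
#' @param relTracerMass Relative standard uncertainty of the tracer mass
#'   taken (difference weighing); default 0.1 %.
#' @return Named numeric vector with components `countsAnalyte`,
#'   `countsTracer`, `tracerActivity`, `tracerMass`, `blank`.
#' @seealso [combinedUncertainty()]
#' @export
uncertaintyBudget <- function(record, K,
                              relTracerActivity = 0.0050 / 2 / 0.4891,
                              relTracerMass = 0.001) {
  stopifnot(is(record, "MeasurementRecord"))
  K <- .asK(K)
  net <- .netTracer(record)
  nprime <- blankEquivalentCounts(K, record)
  netAnalyte <- record@counts210Po - nprime -
    record@bkgRate210Po * record@liveTime
  if (netAnalyte > 0) {
    relA <- sqrt(record@counts210Po) / netAnalyte
    relBlank <- K@uKRel * nprime / netAnalyte
  } else {
    relA <- NA_real_
    relBlank <- NA_real_
  }
  c(countsAnalyte = relA,
    countsTracer = sqrt(record@countsTracer) / net,
    tracerActivity = relTracerActivity,
    tracerMass = relTracerMass,
    blank = relBlank)
}

#' Combine relative uncertainty components in quadrature
#'
#' `u = sqrt(sum(components^2))`, the GUM quadrature sum of independent
#' relative standard uncertainties.
#'
#' @param components Numeric vector of relative uncertainties (all >= 0).
#' @return Combined relative standard uncertainty (fraction); `NA` if any
#'   component is `NA`.
#' @examples
#' combinedUncertainty(c(0.03, 0.04))  # 0.05
#' @export
combinedUncertainty <- function(components) {
  components <- as.numeric(components)
  if (anyNA(components)) return(NA_real_)
  if (any(components < 0))
    stop("uncertainty components must be >= 0", call. = FALSE)
  sqrt(sum(components^2))
}

#' Expanded uncertainty at approximately 95 % confidence
#'
#' `U = 2 * u * C`, coverage factor k = 2.
#'
#' @param concentration C_lab, Bq/l (>= 0).
#' @param uRel Relative combined standard uncertainty (fraction, >= 0).
#' @return Expanded uncertainty, Bq/l.
#' @examples
#' expandedUncertainty(1, 0.05)  # 0.1
#' @export
expandedUncertainty <- function(concentration, uRel) {
  .checkScalar(concentration, "concentration", nonneg = TRUE)
  .checkScalar(uRel, "uRel", nonneg = TRUE)
  2 * uRel * concentration
}

#' Full per-sample evaluation
#'
#' Runs the whole chain for one sample: blank-equivalent counts, activity
#' concentration, uncertainty budget, expanded uncertainty, MDC, tracer
#' recovery (when the efficiency is known) and the below-MDC flag, bundled
#' into an [ActivityResult-class].
#'
#' @param record A [MeasurementRecord-class].
#' @param K A [KConstant-class] or bare Bq value.
#' @param config An [assayConfig()] list controlling the MDC formula, decay
#'   correction, recovery counting mode and budget defaults.
#' @return An [ActivityResult-class] object.
#' @examples
#' r <- measurementRecord(1100, 4500, 518400, 0.0489, 0.5,
#'                        bkgRate210Po = 3e-6, bkgRateTracer = 3e-6,
#'                        efficiency = 0.25)
#' analyzeSample(r, K = kConstant(7e-4, 0.1, 5))
#' @export
analyzeSample <- function(record, K, config = assayConfig()) {
  stopifnot(is(record, "MeasurementRecord"))
  K <- .asK(K)
  C <- activityConcentration(record, K,
                             decayCorrect = config$decayCorrect,
                             delayDays = config$delayDays)
  budget <- uncertaintyBudget(record, K,
                              relTracerActivity = config$relTracerActivity,
                              relTracerMass = config$relTracerMass)
  u <- combinedUncertainty(budget)
  U <- if (!is.na(u) && C > 0) expandedUncertainty(C, u) else NA_real_
  m <- mdc(record, K, formula = config$mdcFormula)
  R <- if (!is.na(record@efficiency))
    tracerRecovery(record, netCounts = config$recoveryNetCounts)
  else NA_real_
  new("ActivityResult", sampleId = record@sampleId, concentration = C,
      uRel = u, expanded = U, mdc = m, recovery = R, belowMdc = C < m,
      kValue = K@K, configDigest = configDigest(config))
}
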