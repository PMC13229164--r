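# Worker-level reporting: daily excreted activity, ratio-to-median
# normalization and coefficient-based dose screening. Workers are referred
# to only by anonymized codes.

#' Daily excreted activity
#'
#' `A_day = C * V_24h`: the 210Po activity excreted per day, in Bq/d. The
#' concentration refers to the analyzed aliquot's parent 24-hour sample, so
#' the total daily volume multiplies regardless of the aliquot taken for
#' radiochemistry.
#'
#' @param concentration C in Bq/l.
#' @param volume24h Total 24-hour urine volume, litres (> 0).
#' @return Excreted activity, Bq/d.
#' @examples
#' dailyExcretion(0.02, 1.5)  # 0.03 Bq/d
#' @export
dailyExcretion <- function(concentration, volume24h) {
  stopifnot(is.numeric(concentration), is.numeric(volume24h))
  if (any(!is.finite(volume24h)) || any(volume24h <= 0))
    stop("'volume24h' must be > 0 (l)", call. = FALSE)
  concentration * volume24h
}

#' Normalize excretion values to a group median
#'
#' Divides each subject value by the median daily excreted activity of a
#' reference group (e.g. all samples collected in the same department over
#' the monitoring period). The median uses the mean-of-middle-two
#' convention for even group sizes. Dietary 210Po is deliberately not
#' subtracted before normalization.
#'
#' @param group Daily excreted activities of the reference group, Bq/d
#'   (non-empty, median > 0).
#' @param subject Values to normalize, Bq/d; defaults to the group itself.
#' @return A list with `ratios` (subject / median) and `median` (A_Me,
#'   Bq/d).
#' @examples
#' normalizeToMedian(c(1, 2, 3), 3)  # ratio 1.5
#' @export
normalizeToMedian <- function(group, subject = group) {
  group <- as.numeric(group)
  if (!length(group) || anyNA(group))
    stop("'group' must be non-empty with no missing values", call. = FALSE)
  aMe <- stats::median(group)
  if (aMe == 0)
    stop("group median is zero; ratios are undefined", call. = FALSE)
  list(ratios = as.numeric(subject) / aMe, median = aMe)
}

#' Coefficient-based committed-dose screening
#'
#' `dose = intake * e(g)` with the committed-effective-dose coefficient per
#' unit intake. The default coefficient, 1.1 uSv/Bq, applies to inhaled
#' 210Po of moderate absorption (Type M) at 5 um AMAD. This is a screening
#' product only: it converts an externally estimated intake, not a
#' bioassay-derived one, since intake reconstruction from excretion
#' requires biokinetic modelling outside this package's scope.
#'
#' @param intake Intake, Bq (>= 0).
#' @param doseCoefficient e(g) in Sv/Bq; default `1.1e-6` (1.1 uSv/Bq).
#' @return Committed effective dose, Sv.
#' @examples
#' doseScreening(100)  # 1.1e-4 Sv = 110 uSv
#' @export
doseScreening <- function(intake, doseCoefficient = 1.1e-6) {
  stopifnot(is.numeric(intake))
  if (any(!is.finite(intake)) || any(intake < 0))
    stop("'intake' must be >= 0 (Bq)", call. = FALSE)
  .checkScalar(doseCoefficient, "doseCoefficient", positive = TRUE)
  intake * doseCoefficient
}
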