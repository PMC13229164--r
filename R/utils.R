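# internal scalar/vector argument checks; stop() messages name the offending
# argument so pipeline errors can be traced back to a sample

.checkScalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         allowNA = FALSE) {
  if (length(x) != 1L)
    stop(sprintf("'%s' must be a single value", name), call. = FALSE)
  if (is.na(x)) {
    if (allowNA) return(invisible(x))
    stop(sprintf("'%s' must not be NA", name), call. = FALSE)
  }
  if (!is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

.isWholeNumber <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}

#' Physical constants for the polonium urinalysis method
#'
#' Nominal alpha-line energies of the tracer (209Po) and analyte (210Po),
#' the 210Po half-life, and the default committed-effective-dose coefficient
#' used for screening.
#'
#' @return `poAlphaLines()` returns a named numeric vector (keV) with
#'   elements `tracer` and `analyte`; `po210HalfLifeDays()` the 210Po
#'   half-life in days; `po210DecayConstantPerDay()` the corresponding decay
#'   constant (1/day).
#' @examples
#' poAlphaLines()
#' po210HalfLifeDays()
#' @export
poAlphaLines <- function() {
  c(tracer = 4883.0, analyte = 5304.3)
}

#' @rdname poAlphaLines
#' @export
po210HalfLifeDays <- function() 138.4

#' @rdname poAlphaLines
#' @export
po210DecayConstantPerDay <- function() log(2) / po210HalfLifeDays()

# report rounding conventions: concentrations to 4 decimals (Bq/l),
# percentages to one decimal; relative bias to one decimal below 10 %,
# whole percent at >= 10 %

# half-up on the magnitude (the convention of printed report tables, unlike
# base round()'s round-half-to-even); small epsilon absorbs binary
# representation error of decimal inputs
.roundHalfUp <- function(x, digits) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-8) / s
}

#' Report rounding conventions
#'
#' Rounding used in printed reports (half-up on the magnitude): activity
#' concentrations to four decimals (Bq/l), generic percentages and scores
#' to one decimal, and relative bias to one decimal below 10 % in magnitude
#' but whole percent at 10 % and above.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @examples
#' roundConcentration(0.0119239)
#' roundBias(c(-3.06, 10.91))
#' @export
roundConcentration <- function(x) .roundHalfUp(x, 4L)

#' @rdname roundConcentration
#' @export
roundPercent <- function(x) .roundHalfUp(x, 1L)

#' @rdname roundConcentration
#' @export
roundScore <- function(x) .roundHalfUp(x, 1L)

#' @rdname roundConcentration
#' @export
roundBias <- function(x) {
  ifelse(abs(x) < 10, .roundHalfUp(x, 1L), .roundHalfUp(x, 0L))
}
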