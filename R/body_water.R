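# Body-water 2H enrichment via the acetone-exchange standard curve.
#
# Acetone incubated with serum exchanges hydrogens with body water; the
# 2H1-acetone fraction is linear in the water 2H fraction over the working
# range. A serial dilution of heavy water in naturally labelled water gives
# the standard curve; serum measurements are inverted through it.

#' Fit the acetone body-water standard curve
#'
#' Ordinary least-squares line `acetone_h1 = slope * known_fraction +
#' intercept` through calibration standards of known heavy-water fraction.
#' The intercept is estimated (not forced through zero) because natural 2H
#' background gives a nonzero blank.
#'
#' @param standards `data.frame` with columns `known_fraction` (in `[0,1)`)
#'   and `acetone_h1_fraction` (in `[0,1)`); >= 2 distinct fractions.
#' @return A `"linear_calibration"` object; a non-positive slope is flagged
#'   with a warning.
#' @examples
#' std <- data.frame(known_fraction = c(0, 0.01, 0.02, 0.04),
#'                   acetone_h1_fraction = c(0.005, 0.0125, 0.020, 0.035))
#' fit_body_water_curve(std)
#' @export
fit_body_water_curve <- function(standards) {
  req <- c("known_fraction", "acetone_h1_fraction")
  if (!is.data.frame(standards) || !all(req %in% names(standards))) {
    stop("'standards' needs columns known_fraction, acetone_h1_fraction",
         call. = FALSE)
  }
  f <- standards$known_fraction
  a <- standards$acetone_h1_fraction
  if (any(f < 0 | f >= 1) || any(a < 0 | a >= 1)) {
    stop("standard fractions must lie in [0, 1)", call. = FALSE)
  }
  curve <- fit_linear_calibration(f, a)
  if (!curve$slope_positive) {
    warning("body-water curve has non-positive slope; check standards",
            call. = FALSE)
  }
  curve
}

#' Invert the standard curve to body-water enrichment
#'
#' Substitutes a measured 2H1-acetone fraction into the standard curve and
#' returns the implied body-water 2H fraction, clamped to `[0, 1]`. Blanks
#' can scatter below the intercept, so values inverting negative are clamped
#' to 0 with a warning rather than erroring.
#'
#' @param acetone_h1 Measured 2H1-acetone fraction(s).
#' @param curve Curve from [fit_body_water_curve()] (slope must be > 0).
#' @return Body-water fraction(s) in `[0, 1]`.
#' @export
body_water_enrichment <- function(acetone_h1, curve) {
  bw <- invert_calibration(curve, acetone_h1)
  n_clamped <- sum(bw < 0 | bw > 1, na.rm = TRUE)
  if (n_clamped > 0L) {
    warning(sprintf("%d body-water value(s) outside [0, 1] clamped",
                    n_clamped), call. = FALSE)
  }
  pmin(pmax(bw, 0), 1)
}
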