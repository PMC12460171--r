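# Shared linear calibration (ordinary least squares with intercept).

#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit `y = slope * x + intercept`, optionally with
#' 1/x weighting for wide dynamic ranges. Used for the acetone body-water
#' standard curve and for concentration calibration.
#'
#' @param x Known values (>= 2 distinct).
#' @param y Measured responses, same length.
#' @param weighting `"none"` (default) or `"1/x"` (zero-x points get the
#'   smallest positive x's weight).
#' @return Object of class `"linear_calibration"`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, `slope_se`, `slope_positive`.
#' @export
fit_linear_calibration <- function(x, y, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || length(unique(x)) < 2L) {
    stop("calibration needs >= 2 distinct x values", call. = FALSE)
  }
  w <- NULL
  if (weighting == "1/x") {
    xm <- ifelse(x > 0, x, min(x[x > 0]))
    w <- 1 / xm
  }
  fit <- lm(y ~ x, weights = w)
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else as.numeric(rss < 1e-24)
  slope <- unname(coef(fit)[2L])
  # collinear standards are legitimate; silence the perfect-fit warning
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["x", "Std. Error"]),
    error = function(e) NA_real_)
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 n_points = length(x),
                 slope_se = unname(se),
                 slope_positive = slope > 0,
                 weighting = weighting),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf(
    "<linear_calibration> y = %.6g * x + %.6g  (r^2 = %.4f, n = %d%s)\n",
    x$slope, x$intercept, x$r_squared, x$n_points,
    if (!x$slope_positive) ", WARNING: non-positive slope" else ""))
  invisible(x)
}

#' Invert a linear calibration
#'
#' Returns `(response - intercept) / slope`; the inverse prediction of the
#' known quantity from a measured response.
#'
#' @param curve A [fit_linear_calibration()] object.
#' @param response Measured response(s).
#' @return Numeric vector of inverse-predicted values (unclamped).
#' @export
invert_calibration <- function(curve, response) {
  stopifnot(inherits(curve, "linear_calibration"))
  if (curve$slope <= 0) {
    stop("calibration slope must be > 0 for inversion", call. = FALSE)
  }
  (response - curve$intercept) / curve$slope
}
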