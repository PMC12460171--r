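# Whole-body fatty-acid oxidation from 13CO2 breath traces.

#' Construct a 13CO2 trace
#'
#' One animal's time series of the 13CO2 / total-CO2 ratio after an oral
#' 13C-substrate dose. The baseline is the natural 13C abundance the
#' calorimeter is calibrated to (1.1% by default), not a per-animal
#' pre-dose mean.
#'
#' @param animal_id Identifier.
#' @param times Minutes since dose, strictly increasing.
#' @param ratios 13CO2 / total-CO2 fractions in `[0, 1]`.
#' @param baseline_fraction Natural-abundance 13C fraction (default 0.011).
#' @return Object of class `"co2_trace"`.
#' @export
co2_trace <- function(animal_id, times, ratios, baseline_fraction = 0.011) {
  if (length(times) != length(ratios)) {
    stop("'times' and 'ratios' must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (any(ratios < 0 | ratios > 1)) {
    stop("'ratios' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(animal_id = as.character(animal_id), times = times,
                 ratios = ratios, baseline_fraction = baseline_fraction),
            class = "co2_trace")
}

#' Construct a circulating-substrate enrichment trace
#'
#' Serial measurements of circulating un-esterified 13C-substrate
#' enrichment for one animal, used to normalize the CO2 excess.
#'
#' @param animal_id Identifier.
#' @param times Minutes since dose, strictly increasing.
#' @param enrichments Enrichment fractions in `[0, 1]`.
#' @return Object of class `"substrate_trace"`.
#' @export
substrate_trace <- function(animal_id, times, enrichments) {
  if (length(times) != length(enrichments)) {
    stop("'times' and 'enrichments' must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (any(enrichments < 0 | enrichments > 1)) {
    stop("'enrichments' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(animal_id = as.character(animal_id), times = times,
                 enrichments = enrichments),
            class = "substrate_trace")
}

#' Baseline-corrected 13CO2 excess
#'
#' Subtracts the natural-abundance baseline from each ratio; negative
#' excursions (measurement noise below baseline) are floored at 0 and the
#' number of floored points is attached as attribute `"n_floored"` and
#' warned about.
#'
#' @param trace A [co2_trace()].
#' @return Numeric vector of excess fractions, one per time point.
#' @export
excess_co2 <- function(trace) {
  stopifnot(inherits(trace, "co2_trace"))
  ex <- trace$ratios - trace$baseline_fraction
  n_floored <- sum(ex < 0)
  if (n_floored > 0L) {
    warning(sprintf("animal '%s': %d excess value(s) below baseline floored",
                    trace$animal_id, n_floored), call. = FALSE)
    ex <- pmax(ex, 0)
  }
  attr(ex, "n_floored") <- n_floored
  ex
}

#' Slope of the 13CO2 rise up to its maximum
#'
#' Finds the earliest time at which the baseline-corrected excess attains
#' its maximum (ties resolve to the earliest point) and fits an ordinary
#' least-squares line to excess versus time over all points from the first
#' through that maximum. The slope summarizes how fast the animal converts
#' the dosed substrate to CO2.
#'
#' @param trace A [co2_trace()] with >= 3 points.
#' @return List: `slope` (fraction per minute), `time_of_max` (minutes),
#'   `n_points` used in the fit.
#' @export
slope_to_max <- function(trace) {
  stopifnot(inherits(trace, "co2_trace"))
  if (length(trace$times) < 3L) {
    stop("slope_to_max needs at least 3 time points", call. = FALSE)
  }
  ex <- pmax(trace$ratios - trace$baseline_fraction, 0)
  i_max <- which.max(ex)  # which.max takes the earliest of tied maxima
  if (i_max == 1L) {
    stop(sprintf("no rise: maximum excess at the first time point (animal '%s')",
                 trace$animal_id), call. = FALSE)
  }
  tt <- trace$times[1:i_max]
  yy <- ex[1:i_max]
  slope <- unname(coef(lm(yy ~ tt))[2L])
  list(slope = slope, time_of_max = trace$times[i_max], n_points = i_max)
}

#' Normalize 13CO2 excess to circulating substrate enrichment
#'
#' Divides the excess at each CO2 time point by the circulating substrate
#' enrichment linearly interpolated to that time, removing differences in
#' precursor availability between animals. Extrapolation outside the
#' substrate time range is refused; points where the interpolated
#' enrichment falls at or below `enrichment_floor` are dropped with a
#' warning (division by a near-zero precursor is meaningless).
#'
#' @param trace A [co2_trace()].
#' @param substrate A [substrate_trace()] covering the trace's time span.
#' @param enrichment_floor Minimum usable substrate enrichment
#'   (default 0.001).
#' @return `data.frame`: `time_min`, `excess`, `substrate_enrichment`,
#'   `normalized` (floored points omitted).
#' @export
normalize_oxidation <- function(trace, substrate, enrichment_floor = 0.001) {
  stopifnot(inherits(trace, "co2_trace"), inherits(substrate, "substrate_trace"))
  if (min(trace$times) < min(substrate$times) ||
      max(trace$times) > max(substrate$times)) {
    stop(sprintf(
      "substrate enrichment for animal '%s' covers [%g, %g] min but CO2 trace spans [%g, %g] min; extrapolation refused",
      trace$animal_id, min(substrate$times), max(substrate$times),
      min(trace$times), max(trace$times)), call. = FALSE)
  }
  ex <- pmax(trace$ratios - trace$baseline_fraction, 0)
  s <- approx(substrate$times, substrate$enrichments, xout = trace$times)$y
  keep <- s > enrichment_floor
  if (any(!keep)) {
    warning(sprintf(
      "animal '%s': %d point(s) dropped (substrate enrichment <= %g)",
      trace$animal_id, sum(!keep), enrichment_floor), call. = FALSE)
  }
  data.frame(time_min = trace$times[keep], excess = ex[keep],
             substrate_enrichment = s[keep],
             normalized = ex[keep] / s[keep])
}
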