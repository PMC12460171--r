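# Calibration-curve quantitation and normalized lipogenesis readouts.

#' Fit a concentration calibration curve
#'
#' OLS line `response = slope * concentration + intercept` through authentic
#' standards; `weighting = "1/x"` is available for wide dynamic ranges.
#' Invert with [invert_calibration()] to quantify unknowns.
#'
#' @param standards `data.frame` with columns `known_concentration` (uM,
#'   >= 0) and `response` (ion count, >= 0); >= 2 distinct concentrations.
#' @param weighting `"none"` or `"1/x"`.
#' @return A `"linear_calibration"` object.
#' @examples
#' std <- data.frame(known_concentration = c(0, 10, 20),
#'                   response = c(0, 1000, 2000))
#' invert_calibration(fit_concentration_curve(std), 1500)  # 15 uM
#' @export
fit_concentration_curve <- function(standards, weighting = c("none", "1/x")) {
  req <- c("known_concentration", "response")
  if (!is.data.frame(standards) || !all(req %in% names(standards))) {
    stop("'standards' needs columns known_concentration, response",
         call. = FALSE)
  }
  if (any(standards$known_concentration < 0) || any(standards$response < 0)) {
    stop("standards must be non-negative", call. = FALSE)
  }
  fit_linear_calibration(standards$known_concentration, standards$response,
                         weighting = match.arg(weighting))
}

#' Tissue concentration from an extract concentration
#'
#' Computes `extract concentration (uM) x extraction volume (ul) / tissue
#' mass (mg)`, the conventional per-mass scaling of an extract
#' measurement. The number is returned on this printed scale with an
#' explicit unit label: dimensionally, uM x ul / mg is nmol/g (the
#' default label); the `"umol/g"` label is available where that convention
#' is preferred for the same numeric expression.
#'
#' @param sample_conc Extract concentration, uM.
#' @param extraction_volume Extraction solvent volume, ul (> 0).
#' @param tissue_mass Tissue wet mass, mg (> 0).
#' @param unit_label `"nmol/g"` (dimensionally consistent default) or
#'   `"umol/g"`.
#' @return Numeric vector with attribute `"unit"`.
#' @examples
#' tissue_concentration(50, 800, 20)  # 2000 nmol/g
#' @export
tissue_concentration <- function(sample_conc, extraction_volume, tissue_mass,
                                 unit_label = c("nmol/g", "umol/g")) {
  unit_label <- match.arg(unit_label)
  if (any(extraction_volume <= 0)) {
    stop("'extraction_volume' must be > 0", call. = FALSE)
  }
  if (any(tissue_mass <= 0)) stop("'tissue_mass' must be > 0", call. = FALSE)
  if (any(sample_conc < 0)) stop("'sample_conc' must be >= 0", call. = FALSE)
  out <- sample_conc * extraction_volume / tissue_mass
  attr(out, "unit") <- unit_label
  out
}

#' Normalize a lipogenesis readout to precursor acetyl-CoA labelling
#'
#' Divides a labelled fatty-acid readout (ion count or enrichment) by the
#' 13C fractional labelling of hepatic acetyl-CoA, removing differences in
#' precursor-pool enrichment between animals so the ratio reflects
#' synthesis itself.
#'
#' @param labelled_fa Labelled fatty-acid ion count or enrichment (>= 0).
#' @param acetylcoa_fraction Hepatic acetyl-CoA 13C fractional labelling,
#'   in (0, 1].
#' @return Normalized value(s).
#' @export
normalize_to_acetylcoa <- function(labelled_fa, acetylcoa_fraction) {
  if (any(!is.finite(acetylcoa_fraction)) || any(acetylcoa_fraction <= 0) ||
      any(acetylcoa_fraction > 1)) {
    stop("'acetylcoa_fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (any(labelled_fa < 0)) stop("'labelled_fa' must be >= 0", call. = FALSE)
  labelled_fa / acetylcoa_fraction
}
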