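# De novo lipogenesis from heavy-water labelling of palmitate.
#
# Model: newly synthesized palmitate incorporates deuterium at n
# exchangeable hydrogen positions, each labelled independently at the
# body-water 2H fraction (binomial labelling); pre-existing palmitate is
# unlabelled. Then
#   DNL fraction = 2H enrichment / (body water x n)          (precursor norm)
#   H2/H1        = ((n - 1)/2) x BW/(1 - BW)                 (binomial ratio)
# so n is identifiable per sample from the doubly- to singly-labelled
# isotopomer ratio, and the DNL fraction follows from the enrichment.

#' Estimate exchangeable hydrogens from the H2/H1 isotopomer ratio
#'
#' Under binomial labelling of n sites at probability BW, the ratio of the
#' doubly- to singly-labelled fractions is `((n-1)/2) * BW/(1-BW)`.
#' Inverting: `n = 1 + 2 * ratio * (1 - BW)/BW`. Estimated per sample, not
#' pooled, so each animal's own isotopomer pattern sets its n.
#'
#' @param h2_to_h1_ratio Ratio of corrected 2H2 to 2H1 fractions (>= 0).
#' @param body_water Body-water 2H fraction, strictly in (0, 1).
#' @return Estimated n (>= 1); values below 1 are clamped to 1 with a
#'   warning.
#' @examples
#' exchangeable_hydrogens(0.4375, 0.04)  # 22
#' @export
exchangeable_hydrogens <- function(h2_to_h1_ratio, body_water) {
  if (any(!is.finite(body_water)) || any(body_water <= 0) ||
      any(body_water >= 1)) {
    stop("'body_water' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(h2_to_h1_ratio)) || any(h2_to_h1_ratio < 0)) {
    stop("'h2_to_h1_ratio' must be finite and >= 0", call. = FALSE)
  }
  n <- 1 + 2 * h2_to_h1_ratio * (1 - body_water) / body_water
  if (any(n < 1)) {
    warning("estimated n below 1 clamped to 1", call. = FALSE)
    n <- pmax(n, 1)
  }
  n
}

#' Fraction of palmitate newly synthesized
#'
#' `DNL = enrichment / (body_water * n)`: the measured deuterium enrichment
#' normalized by its theoretical maximum, reached when the whole pool is
#' newly made. Values above 1 indicate a calibration or QC problem and are
#' returned as-is (flag, don't clamp, so QC can catch them).
#'
#' @param h_enrichment Deuterium enrichment ([deuterium_enrichment()]).
#' @param body_water Body-water 2H fraction (> 0).
#' @param n Exchangeable hydrogens (>= 1).
#' @return DNL fraction (>= 0, not clamped above).
#' @examples
#' dnl_fraction(0.22, 0.025, 22)  # 0.4
#' @export
dnl_fraction <- function(h_enrichment, body_water, n) {
  if (any(h_enrichment < 0)) {
    stop("'h_enrichment' must be >= 0", call. = FALSE)
  }
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  denom <- body_water * n
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    stop("zero or invalid denominator: body_water * n must be > 0",
         call. = FALSE)
  }
  h_enrichment / denom
}

#' DNL rate per hour
#'
#' Divides the DNL fraction by the time elapsed since heavy-water
#' administration. Provide either `dose_time` and `collection_time`
#' (anything `as.POSIXct` accepts) or `elapsed_hours` directly.
#'
#' @param dnl DNL fraction(s).
#' @param dose_time,collection_time Timestamps; collection must be after
#'   dose.
#' @param elapsed_hours Alternative to the timestamp pair.
#' @return List: `rate_per_hour`, `elapsed_hours`.
#' @examples
#' dnl_rate(0.4, "2024-05-01 18:00:00", "2024-05-02 09:00:00")
#' @export
dnl_rate <- function(dnl, dose_time = NULL, collection_time = NULL,
                     elapsed_hours = NULL) {
  if (is.null(elapsed_hours)) {
    if (is.null(dose_time) || is.null(collection_time)) {
      stop("provide dose_time and collection_time, or elapsed_hours",
           call. = FALSE)
    }
    elapsed_hours <- as.numeric(difftime(as.POSIXct(collection_time, tz = "UTC"),
                                         as.POSIXct(dose_time, tz = "UTC"),
                                         units = "hours"))
  }
  if (any(!is.finite(elapsed_hours)) || any(elapsed_hours <= 0)) {
    stop("elapsed time must be positive", call. = FALSE)
  }
  list(rate_per_hour = dnl / elapsed_hours, elapsed_hours = elapsed_hours)
}

#' Full per-sample DNL calculation from a corrected MID
#'
#' Chains the enrichment, exchangeable-hydrogen and DNL-fraction steps for
#' one sample. Samples whose 2H1 fraction is zero have an undefined H2/H1
#' ratio and are returned with `NA` estimates and qc flag `"h1_zero"`;
#' DNL fractions above 1 get flag `"dnl_gt_1"`.
#'
#' @param mid Corrected MID (>= 4 entries).
#' @param body_water Body-water 2H fraction in (0, 1).
#' @param elapsed_hours Hours since dose (optional; rate is `NA` without it).
#' @param sample_id Optional identifier carried into the result.
#' @return One-row `data.frame`: `sample_id`, `h_enrichment`, `body_water`,
#'   `n_exchangeable`, `dnl_fraction`, `dnl_rate_per_hour`, `elapsed_hours`,
#'   `qc_flags`.
#' @export
dnl_from_mid <- function(mid, body_water, elapsed_hours = NA_real_,
                         sample_id = NA_character_) {
  enr <- deuterium_enrichment(mid)
  flags <- character(0)
  if (enr$h1 <= 0) {
    return(data.frame(sample_id = sample_id, h_enrichment = enr$enrichment,
                      body_water = body_water, n_exchangeable = NA_real_,
                      dnl_fraction = NA_real_, dnl_rate_per_hour = NA_real_,
                      elapsed_hours = elapsed_hours, qc_flags = "h1_zero",
                      stringsAsFactors = FALSE))
  }
  n <- exchangeable_hydrogens(enr$h2 / enr$h1, body_water)
  dnl <- dnl_fraction(enr$enrichment, body_water, n)
  if (dnl > 1) flags <- c(flags, "dnl_gt_1")
  rate <- if (is.finite(elapsed_hours) && elapsed_hours > 0) {
    dnl_rate(dnl, elapsed_hours = elapsed_hours)$rate_per_hour
  } else {
    NA_real_
  }
  data.frame(sample_id = sample_id, h_enrichment = enr$enrichment,
             body_water = body_water, n_exchangeable = n,
             dnl_fraction = dnl, dnl_rate_per_hour = rate,
             elapsed_hours = elapsed_hours,
             qc_flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
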