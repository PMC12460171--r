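# Natural-abundance correction of mass-isotopomer distributions.
#
# High-resolution assumption: only the tracer element's natural abundance is
# corrected. At the orbitrap resolution these data come from (140,000),
# isotopologues of non-tracer elements are mass-resolved from the tracer
# series, so their abundance never leaks into the measured M+i peaks.

#' Natural-abundance model for a tracer element
#'
#' Bundles the tracer element, the natural fraction of its heavy isotope,
#' and the isotopic purity of the tracer. Defaults: 1.1% for 13C (the
#' conventional natural abundance, also the 13CO2 calibration baseline) and
#' 0.0156% for 2H. Purity defaults to 1 (no purity correction).
#'
#' @param tracer_element `"C"` or `"H"`.
#' @param heavy_fraction Natural fraction of the heavy isotope, in `[0, 0.5)`.
#'   `NULL` selects the element default (C: 0.011, H: 0.000156).
#' @param tracer_purity Isotopic purity of the tracer, in `(0, 1]`.
#' @return An object of class `"na_model"`.
#' @examples
#' na_model("C")
#' na_model("H", tracer_purity = 0.99)
#' @export
na_model <- function(tracer_element = c("C", "H"), heavy_fraction = NULL,
                     tracer_purity = 1) {
  tracer_element <- match.arg(tracer_element)
  if (is.null(heavy_fraction)) {
    heavy_fraction <- switch(tracer_element, C = 0.011, H = 0.000156)
  }
  if (!is.numeric(heavy_fraction) || length(heavy_fraction) != 1L ||
      heavy_fraction < 0 || heavy_fraction >= 0.5) {
    stop("'heavy_fraction' must be a single value in [0, 0.5)", call. = FALSE)
  }
  if (!is.numeric(tracer_purity) || length(tracer_purity) != 1L ||
      tracer_purity <= 0 || tracer_purity > 1) {
    stop("'tracer_purity' must be a single value in (0, 1]", call. = FALSE)
  }
  structure(list(tracer_element = tracer_element,
                 heavy_fraction = heavy_fraction,
                 tracer_purity = tracer_purity),
            class = "na_model")
}

#' @export
print.na_model <- function(x, ...) {
  cat(sprintf("<na_model> tracer %s, heavy fraction %.6g, purity %.4g\n",
              x$tracer_element, x$heavy_fraction, x$tracer_purity))
  invisible(x)
}

#' Natural mass-isotopomer distribution of n atoms
#'
#' The MID of a molecule with `n_atoms` tracer-element atoms and no tracer:
#' entry i is the binomial probability of i heavy atoms at the natural heavy
#' fraction, `choose(n, i) a^i (1-a)^(n-i)`.
#'
#' @param n_atoms Number of tracer-element atoms (>= 0).
#' @param model An [na_model()].
#' @return Numeric vector of length `n_atoms + 1` summing to 1.
#' @examples
#' natural_mid(2, na_model("C"))
#' @export
natural_mid <- function(n_atoms, model) {
  stopifnot(inherits(model, "na_model"))
  n_atoms <- check_count(n_atoms, "n_atoms")
  dbinom(0:n_atoms, n_atoms, model$heavy_fraction)
}

#' Build the natural-abundance correction matrix
#'
#' Column j is the measured MID expected from a molecule carrying exactly j
#' tracer labels: the natural-abundance distribution of the remaining
#' `n_atoms - j` atoms, shifted down by the number of labels actually
#' retained (binomial in the tracer purity). With purity 1 the matrix is
#' lower-triangular with unit diagonal contributions shifted by j; with
#' `heavy_fraction = 0` and purity 1 it is the identity.
#'
#' @inheritParams natural_mid
#' @return Dense `(n_atoms+1) x (n_atoms+1)` matrix; each column sums to 1.
#' @seealso [correct_mid()] for the inversion.
#' @export
build_correction_matrix <- function(n_atoms, model) {
  stopifnot(inherits(model, "na_model"))
  n_atoms <- check_count(n_atoms, "n_atoms")
  k <- n_atoms + 1L
  A <- matrix(0, k, k)
  for (j in 0:n_atoms) {
    nat <- dbinom(0:(n_atoms - j), n_atoms - j, model$heavy_fraction)
    pur <- dbinom(0:j, j, model$tracer_purity)
    col <- numeric(k)
    for (r in 0:j) {
      if (pur[r + 1L] == 0) next
      idx <- r + 0:(n_atoms - j) + 1L
      col[idx] <- col[idx] + pur[r + 1L] * nat
    }
    A[, j + 1L] <- col
  }
  A
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves `min ||A x - measured||_2` subject to `x >= 0`, where `A` is the
#' correction matrix, then renormalizes `x` to the simplex. Non-negative
#' least squares is used instead of plain matrix inversion because
#' measurement noise can drive naive inversion negative. The Euclidean
#' residual norm is attached as attribute `"residual"`; a residual larger
#' than `residual_warn * ||measured||` triggers a warning.
#'
#' @param measured Raw (or normalized) intensity vector of length
#'   `n_atoms + 1`, entries >= 0, not all zero.
#' @inheritParams natural_mid
#' @param residual_warn Relative residual threshold for the diagnostic
#'   warning.
#' @return Corrected MID: numeric vector of length `n_atoms + 1` summing to
#'   1, with attribute `"residual"`.
#' @examples
#' m <- na_model("C")
#' A <- build_correction_matrix(2, m)
#' correct_mid(as.vector(A %*% c(0.6, 0.3, 0.1)), 2, m)
#' @export
correct_mid <- function(measured, n_atoms, model, residual_warn = 0.01) {
  stopifnot(inherits(model, "na_model"))
  n_atoms <- check_count(n_atoms, "n_atoms")
  if (length(measured) != n_atoms + 1L) {
    stop(sprintf("'measured' must have length n_atoms + 1 = %d, got %d",
                 n_atoms + 1L, length(measured)), call. = FALSE)
  }
  if (anyNA(measured) || any(measured < 0)) {
    stop("'measured' must be non-negative with no missing values",
         call. = FALSE)
  }
  if (all(measured == 0)) {
    stop("empty MID: all measured intensities are zero", call. = FALSE)
  }
  A <- build_correction_matrix(n_atoms, model)
  # scale-invariant solve; lsqnonneg is happier with O(1) inputs
  scale <- sum(measured)
  x <- pracma::lsqnonneg(A, measured / scale)$x
  resid <- sqrt(sum((A %*% x - measured / scale)^2)) * scale
  if (resid > residual_warn * sqrt(sum(measured^2))) {
    warning(sprintf("correction residual %.3g exceeds %.3g of input norm",
                    resid, residual_warn), call. = FALSE)
  }
  fractions <- x / sum(x)
  attr(fractions, "residual") <- resid
  fractions
}

# shared small-integer argument check
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  }
  as.integer(x)
}
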