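# Independent oracles, written from first principles (explicit choose()
# arithmetic and hand formulas), deliberately not via the package's own
# code paths.

# binomial MID of n sites labelled at probability p
oracle_binom_mid <- function(n, p) {
  i <- 0:n
  choose(n, i) * p^i * (1 - p)^(n - i)
}

# two-population mixture MID: (1-f) unlabelled + f binomially labelled
oracle_mixture_mid <- function(f, n, p, length_out = n + 1) {
  mid <- oracle_binom_mid(n, p) * f
  mid[1] <- mid[1] + (1 - f)
  c(mid, numeric(length_out - n - 1))
}

# ratio of the M3-truncated H-weighted sum to the untruncated expectation
# n*p; multiplies the true newly-synthesized fraction in the noise-free
# pipeline estimate
oracle_truncation_factor <- function(n, p) {
  mid <- oracle_binom_mid(n, p)
  (mid[2] + 2 * mid[3] + 3 * mid[4]) / (n * p)
}

# Benjamini-Hochberg step-up computed literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# per-sample DNL estimates through the package pipeline, in memory
# (assemble -> NA-correct -> enrichment -> Eq 3 -> Eq 1), with the
# body-water step run through the acetone calibration
estimate_dnl_cohort <- function(cohort) {
  mids <- suppressWarnings(assemble_mids(cohort$peaks))
  curve <- fit_body_water_curve(cohort$standards)
  bw <- body_water_enrichment(cohort$meta$body_water_acetone_fraction, curve)
  names(bw) <- cohort$meta$sample_id
  res <- do.call(rbind, lapply(mids, function(m) {
    fr <- suppressWarnings(correct_mid(m$intensities, m$n_atoms,
                                       cohort$design$na_model))
    dnl_from_mid(as.vector(fr), bw[[m$sample_id]], elapsed_hours = 15,
                 sample_id = m$sample_id)
  }))
  merge(res, cohort$truth[c("sample_id", "group", "f_true")],
        by = "sample_id")
}

# small valid long-format peak table for one C2 metabolite
make_c2_peaks <- function(sample_id = "s1", intensities = c(900, 90, 10)) {
  data.frame(sample_id = sample_id, metabolite = "glycine_frag",
             formula = "C2H5NO2", tracer_element = "C",
             isotopologue_index = seq_along(intensities) - 1L,
             intensity = intensities, stringsAsFactors = FALSE)
}

# random simplex vector
random_simplex <- function(k) {
  x <- stats::runif(k)
  x / sum(x)
}
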