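test_that("exchangeable hydrogens invert the binomial isotopomer ratio", {
  expect_equal(exchangeable_hydrogens(0.4375, 0.04), 22, tolerance = 1e-12)
  expect_equal(exchangeable_hydrogens(0, 0.02), 1)
  expect_equal(exchangeable_hydrogens(0.0525, 0.005), 21.895,
               tolerance = 1e-12)
  expect_error(exchangeable_hydrogens(0.4, 0), "strictly in")
  expect_error(exchangeable_hydrogens(0.4, 1), "strictly in")
  expect_error(exchangeable_hydrogens(-0.1, 0.02), ">= 0")
})

test_that("binomial ratio identity holds to 1e-12 for n in 2..40", {
  for (n in 2:40) {
    for (p in seq(0.005, 0.06, by = 0.005)) {
      mid <- oracle_binom_mid(n, p)
      ratio <- mid[3] / mid[2]
      expect_equal(ratio, (n - 1) / 2 * p / (1 - p), tolerance = 1e-12)
      expect_equal(exchangeable_hydrogens(ratio, p), n, tolerance = 1e-9)
    }
  }
})

test_that("DNL fraction is the enrichment over its theoretical maximum", {
  expect_equal(dnl_fraction(0.22, 0.025, 22), 0.4)
  expect_equal(dnl_fraction(0, 0.025, 22), 0)
  expect_error(dnl_fraction(0.2, 0, 22), "denominator")
  # homogeneous of degree -1 in body water at fixed enrichment and n
  expect_equal(dnl_fraction(0.22, 0.05, 22),
               dnl_fraction(0.22, 0.025, 22) / 2)
})

test_that("DNL rate divides by elapsed time since dose", {
  r <- dnl_rate(0.4, "2024-05-01 18:00:00", "2024-05-02 09:00:00")
  expect_equal(r$elapsed_hours, 15)
  expect_equal(r$rate_per_hour, 0.4 / 15)  # 0.0267/h over the overnight dose
  expect_equal(dnl_rate(0, elapsed_hours = 15)$rate_per_hour, 0)
  expect_equal(dnl_rate(0.3, elapsed_hours = 6)$rate_per_hour, 0.05)
  expect_error(dnl_rate(0.4, "2024-05-01 18:00:00", "2024-05-01 17:00:00"),
               "positive")
})

test_that("noise-free mixture MIDs recover f up to the truncation factor", {
  for (f in c(0.1, 0.4, 0.8)) {
    for (bw in c(0.01, 0.025)) {
      mid <- oracle_mixture_mid(f, 22, bw)
      res <- dnl_from_mid(mid, bw, elapsed_hours = 15, sample_id = "x")
      expect_equal(res$n_exchangeable, 22, tolerance = 1e-9)
      expect_equal(res$dnl_fraction, f * oracle_truncation_factor(22, bw),
                   tolerance = 1e-10)
    }
  }
  # reference point: f = 0.4, BW = 0.025 -> 0.394 (-1.5% truncation)
  res <- dnl_from_mid(oracle_mixture_mid(0.4, 22, 0.025), 0.025,
                      sample_id = "x")
  expect_equal(res$dnl_fraction, 0.394065, tolerance = 1e-6)
})

test_that("samples with zero H1 are excluded with a reason", {
  res <- dnl_from_mid(c(1, 0, 0, 0), 0.025, sample_id = "unlabelled")
  expect_true(is.na(res$dnl_fraction))
  expect_equal(res$qc_flags, "h1_zero")
  # implausibly high enrichment is flagged, not clamped
  res <- dnl_from_mid(c(0.1, 0.5, 0.3, 0.1), 0.025, sample_id = "hot")
  expect_gt(res$dnl_fraction, 1)
  expect_match(res$qc_flags, "dnl_gt_1")
})
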