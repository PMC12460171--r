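test_that("excess subtracts the natural-abundance baseline and floors at 0", {
  tr <- co2_trace("m1", c(0, 40, 80), c(0.011, 0.0125, 0.011))
  ex <- excess_co2(tr)
  expect_equal(as.vector(ex), c(0, 0.0015, 0))
  expect_equal(attr(ex, "n_floored"), 0L)

  flat <- co2_trace("m2", c(0, 40, 80), rep(0.011, 3))
  expect_equal(as.vector(excess_co2(flat)), rep(0, 3))

  dip <- co2_trace("m3", c(0, 40, 80), c(0.011, 0.0105, 0.012))
  expect_warning(ex <- excess_co2(dip), "1 excess value")
  expect_equal(as.vector(ex), c(0, 0, 0.001))
})

test_that("slope is fitted from t = 0 through the earliest maximum", {
  tr <- co2_trace("m1", c(0, 40, 80, 120),
                  0.011 + c(0, 0.002, 0.004, 0.003))
  s <- slope_to_max(tr)
  expect_equal(s$time_of_max, 80)
  expect_equal(s$slope, 5e-5, tolerance = 1e-12)  # OLS on (0,40,80) by hand
  expect_equal(s$n_points, 3L)

  lin <- co2_trace("m2", seq(0, 160, 40), 0.011 + 2e-5 * seq(0, 160, 40))
  expect_equal(slope_to_max(lin)$slope, 2e-5, tolerance = 1e-12)

  tie <- co2_trace("m3", c(0, 40, 80, 120),
                   0.011 + c(0, 0.002, 0.004, 0.004))
  expect_equal(slope_to_max(tie)$time_of_max, 80)  # earliest of the tie

  flat <- co2_trace("m4", c(0, 40, 80), rep(0.011, 3))
  expect_error(slope_to_max(flat), "no rise")
  expect_error(slope_to_max(co2_trace("m5", c(0, 40), c(0.011, 0.012))),
               "3 time points")
})

test_that("normalization divides by interpolated substrate enrichment", {
  tr <- co2_trace("m1", 60, 0.015)
  # single-point trace is fine for normalization (no slope involved)
  sub <- substrate_trace("m1", c(30, 90), c(0.08, 0.12))
  out <- normalize_oxidation(tr, sub)
  expect_equal(out$substrate_enrichment, 0.10)  # midpoint interpolation
  expect_equal(out$normalized, 0.004 / 0.10)

  tr2 <- co2_trace("m2", c(0, 60, 120), c(0.011, 0.015, 0.013))
  sub1 <- substrate_trace("m2", c(0, 120), c(1, 1))
  out2 <- normalize_oxidation(tr2, sub1)
  expect_equal(out2$normalized, out2$excess)  # unit enrichment = identity

  expect_error(normalize_oxidation(tr2, substrate_trace("m2", c(30, 90),
                                                        c(0.1, 0.1))),
               "extrapolation refused")
  low <- substrate_trace("m2", c(0, 120), c(1, 0))
  expect_warning(out3 <- normalize_oxidation(tr2, low), "dropped")
  expect_equal(nrow(out3), 2L)
})

test_that("normalization is invariant to joint scaling of excess and substrate", {
  tr <- co2_trace("m1", c(0, 60, 120), 0.011 + c(0, 0.004, 0.002))
  sub <- substrate_trace("m1", c(0, 60, 120), c(0.2, 0.1, 0.05))
  base <- normalize_oxidation(tr, sub)
  half <- normalize_oxidation(
    co2_trace("m1", tr$times, 0.011 + (tr$ratios - 0.011) / 2),
    substrate_trace("m1", sub$times, sub$enrichments / 2))
  expect_equal(half$normalized, base$normalized, tolerance = 1e-12)
})

test_that("noise-free rise-then-decay slope is within 5% of the secant", {
  sim <- simulate_co2_traces(noise_cv = 0, n_per_group = 1, seed = 3)
  for (tr in sim$traces) {
    s <- slope_to_max(tr)
    ex <- tr$ratios - tr$baseline_fraction
    secant <- max(ex) / tr$times[which.max(ex)]
    expect_lt(abs(s$slope - secant) / secant, 0.05)
  }
})
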