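test_that("natural MID is the binomial expansion over unlabelled atoms", {
  m <- na_model("C")
  expect_equal(natural_mid(0, m), 1)
  # by hand: (1-a)^2, 2 a (1-a), a^2 at a = 0.011
  expect_equal(natural_mid(2, m),
               c(0.989^2, 2 * 0.011 * 0.989, 0.011^2), tolerance = 1e-12)
  expect_equal(natural_mid(1, m), c(0.989, 0.011))
  expect_equal(sum(natural_mid(16, m)), 1, tolerance = 1e-12)
})

test_that("correction matrix columns are shifted natural MIDs", {
  m <- na_model("C")
  expect_equal(build_correction_matrix(1, m),
               matrix(c(0.989, 0.011, 0, 1), 2, 2), tolerance = 1e-12)
  A <- build_correction_matrix(2, m)
  expect_equal(A[, 1], natural_mid(2, m))
  expect_true(all(A[upper.tri(A)] == 0))  # purity 1 -> lower triangular
  expect_equal(colSums(A), rep(1, 3), tolerance = 1e-12)

  m0 <- na_model("C", heavy_fraction = 0)
  expect_equal(build_correction_matrix(3, m0), diag(4))
})

test_that("tracer impurity shifts column mass below the label count", {
  mp <- na_model("C", heavy_fraction = 0, tracer_purity = 0.9)
  A <- build_correction_matrix(1, mp)
  expect_equal(A[, 2], c(0.1, 0.9))  # one label retained with P = purity
  expect_equal(colSums(A), rep(1, 2), tolerance = 1e-12)
})

test_that("correction inverts the forward convolution", {
  m <- na_model("C")
  A <- build_correction_matrix(2, m)
  out <- correct_mid(as.vector(A %*% c(1, 0, 0)), 2, m)
  expect_equal(as.vector(out), c(1, 0, 0), tolerance = 1e-9)
  expect_lt(attr(out, "residual"), 1e-9)

  out <- correct_mid(as.vector(A %*% c(0.6, 0.3, 0.1)), 2, m)
  expect_equal(as.vector(out), c(0.6, 0.3, 0.1), tolerance = 1e-8)

  m0 <- na_model("C", heavy_fraction = 0)
  raw <- c(5, 3, 2)
  expect_equal(as.vector(correct_mid(raw, 2, m0)), raw / sum(raw))
})

test_that("degenerate inputs error clearly", {
  m <- na_model("C")
  expect_error(correct_mid(c(0, 0, 0), 2, m), "empty MID")
  expect_error(correct_mid(c(1, 0), 2, m), "length")
  expect_error(correct_mid(c(1, -0.1, 0), 2, m), "non-negative")
})

test_that("round-trip holds across random simplex MIDs up to 20 atoms", {
  set.seed(7)
  m <- na_model("C")
  for (i in 1:50) {
    n <- sample(1:20, 1)
    x <- random_simplex(n + 1)
    A <- build_correction_matrix(n, m)
    out <- correct_mid(as.vector(A %*% x), n, m)
    expect_lt(max(abs(as.vector(out) - x)), 1e-8)
  }
})

test_that("noisy inputs stay on the simplex where naive inversion would not", {
  m <- na_model("C")
  # unlabelled C2 standard measured with M1 below its natural share:
  # solve(A) %*% y goes negative, NNLS must not
  y <- c(0.985, 0.014, 0.001)
  A <- build_correction_matrix(2, m)
  naive <- solve(A, y)
  expect_true(any(naive < 0))
  out <- suppressWarnings(correct_mid(y, 2, m))
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1, tolerance = 1e-9)
})

test_that("skipping correction inflates M1 of an unlabelled standard by ~ n*a", {
  m <- na_model("C")
  raw_m1 <- natural_mid(16, m)[2]           # uncorrected M1 fraction
  corrected <- correct_mid(natural_mid(16, m), 16, m)
  expect_equal(as.vector(corrected)[2], 0, tolerance = 1e-9)
  expect_equal(raw_m1, 16 * 0.011, tolerance = 0.2)  # approx n*a
})
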