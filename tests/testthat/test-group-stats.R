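test_that("IQR flagging matches type-7 quartiles by hand", {
  # Q1 = 2, Q3 = 4, IQR = 2, fences (-1, 7): only 100 is out
  expect_equal(flag_outliers_iqr(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_outliers_iqr(rep(3, 6))))
  expect_false(any(flag_outliers_iqr(c(1, 2, 3, 4, 5, 6))))
  expect_warning(f <- flag_outliers_iqr(c(1, 2, 3)), "fewer than 4")
  expect_false(any(f))
})

test_that("no value inside its own fences is ever flagged", {
  set.seed(31)
  for (i in 1:20) {
    v <- stats::rnorm(sample(4:30, 1))
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    inside <- v[v >= fence[1] & v <= fence[2]]
    expect_false(any(flag_outliers_iqr(v)[v %in% inside]))
  }
})

test_that("pooled t-test matches the closed form", {
  null <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                         method = "t_two_sided")
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)

  shift <- compare_groups(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3),
                          method = "t_two_sided")
  # pooled variance 1, t = -1 / sqrt(2/3), df = 4
  t_hand <- -1 / sqrt(2 / 3)
  expect_equal(shift$statistic, t_hand, tolerance = 1e-10)
  expect_equal(shift$p_value, 2 * stats::pt(t_hand, df = 4),
               tolerance = 1e-10)
  expect_equal(shift$p_value, 0.2879, tolerance = 1e-3)

  expect_error(compare_groups(1:9, rep(c("a", "b", "c"), 3),
                              method = "t_two_sided"), "exactly 2")
  expect_error(compare_groups(c(1, 2, 2, 3), rep(c("a", "b"), 2),
                              method = "t_one_sided"),
               "alternative")
})

test_that("Tukey HSD flags a 10-pooled-SD shift and not the null", {
  set.seed(5)
  base <- stats::rnorm(8)
  vals <- c(base, base + 0.2, base + 10 * stats::sd(base))
  g <- rep(c("a", "b", "c"), each = 8)
  out <- compare_groups(vals, g, method = "anova_tukey")
  ac <- out[out$group1 == "c" & out$group2 == "a" |
              out$group1 == "a" & out$group2 == "c", ]
  expect_lt(ac$adjusted_p, 0.001)
  expect_true(all(out$adjusted_p >= out$p_value - 1e-12))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  p <- stats::runif(25)
  expect_equal(adjust_fdr(p), oracle_bh(p))
  # invariant to input order
  perm <- sample(25)
  expect_equal(adjust_fdr(p[perm]), adjust_fdr(p)[perm])
})

test_that("two-sided t holds its nominal level under the null", {
  set.seed(99)
  n_sim <- 400
  rej <- 0L
  for (i in 1:n_sim) {
    out <- compare_groups(stats::rnorm(20), rep(c("a", "b"), each = 10),
                          method = "t_two_sided")
    rej <- rej + (out$p_value < 0.05)
  }
  # binomial 3-sigma band around 5% at 400 simulations
  expect_gt(rej / n_sim, 0.05 - 3 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(rej / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})
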