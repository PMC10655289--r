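test_that("mean estimators from quantiles match hand-derived values", {
  expect_equal(mean_from_quantiles(quantile_report(5, 50, min = 0, max = 10)), 5)
  expect_equal(mean_from_quantiles(quantile_report(2, 50, min = 1, max = 9)), 3.5)
  expect_equal(mean_from_quantiles(quantile_report(10, 50, q1 = 8, q3 = 15)),
               11)
  # five-number form: (a + 2q1 + 2m + 2q3 + b)/8
  expect_equal(mean_from_quantiles(
    quantile_report(10, 50, q1 = 8, q3 = 15, min = 0, max = 20)),
    (0 + 16 + 20 + 30 + 20) / 8)
})

test_that("SD estimators: degenerate spread, large-n limit, quantile oracle", {
  expect_warning(
    s0 <- sd_from_quantiles(quantile_report(10, 50, q1 = 10, q3 = 10)),
    "zero spread")
  expect_equal(s0, 0)
  # as n grows the IQR denominator approaches 2 * qnorm(0.75) = 1.349
  big <- sd_from_quantiles(quantile_report(15, 1e6, q1 = 10, q3 = 20))
  expect_equal(big, 10 / (2 * qnorm(0.75)), tolerance = 1e-4)
  # range form evaluated against the normal-quantile oracle directly
  got <- sd_from_quantiles(quantile_report(20, 100, min = 0, max = 40))
  expect_equal(got, 40 / (2 * qnorm(99.625 / 100.25)), tolerance = 1e-12)
  # simple-rule mode
  expect_equal(
    sd_from_quantiles(quantile_report(20, 100, min = 0, max = 40), "simple"),
    10)
  expect_equal(
    sd_from_quantiles(quantile_report(15, 100, q1 = 10, q3 = 20), "simple"),
    10 / 1.35)
  expect_error(sd_from_quantiles(quantile_report(5, 1, q1 = 4, q3 = 6)),
               "n >= 2")
})

test_that("quantile conversions recover the moments of large normal samples", {
  set.seed(401)
  mu <- 62; sigma <- 13; n <- 1e5
  x <- rnorm(n, mu, sigma)
  q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  rep_iqr <- quantile_report(q[3], n, q1 = q[2], q3 = q[4])
  expect_lt(abs(mean_from_quantiles(rep_iqr) - mu), 0.05 * sigma)
  expect_lt(abs(sd_from_quantiles(rep_iqr) - sigma), 0.1 * sigma)
  expect_lt(abs(sd_from_quantiles(quantile_report(
    q[3], n, min = q[1], max = q[5])) - sigma), 0.1 * sigma)
  # the median/range location estimator is meant for small samples, where
  # the extremes are informative; check it is unbiased over replicates
  errs <- replicate(40, {
    y <- rnorm(100, mu, sigma)
    mean_from_quantiles(quantile_report(median(y), 100,
                                        min = min(y), max = max(y))) - mu
  })
  expect_lt(abs(mean(errs)), 0.05 * sigma)
})

test_that("a median without any spread is rejected", {
  expect_error(quantile_report(5, 10), "median alone")
  expect_error(quantile_report(5, 10, q1 = 4), "both q1 and q3")
  expect_error(quantile_report(5, 10, q1 = 6, q3 = 7), "ordered")
})

test_that("arm pooling reproduces concatenated-sample moments", {
  # degenerate arms {0,0} and {10,10}: brute-force sd of {0,0,10,10}
  pooled <- combine_arms(summary_stat(0, 0, 2), summary_stat(10, 0, 2))
  expect_equal(pooled$mean, 5)
  expect_equal(pooled$sd, sd(c(0, 0, 10, 10)))
  expect_identical(pooled$source, "combined_arms")
  # equal arms: sd = 2 * sqrt(98/99)
  eq <- combine_arms(summary_stat(10, 2, 50), summary_stat(10, 2, 50))
  expect_equal(eq$mean, 10)
  expect_equal(eq$sd, 2 * sqrt(98 / 99))
  # random partitions of one raw sample
  set.seed(402)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1), mean = runif(1, -5, 80), sd = runif(1, 0.5, 20))
    k <- sample(2:(length(x) - 2), 1)
    a <- x[1:k]; b <- x[-(1:k)]
    got <- combine_arms(summary_stat(mean(a), sd(a), length(a)),
                        summary_stat(mean(b), sd(b), length(b)))
    expect_equal(got$mean, mean(x), tolerance = 1e-12)
    expect_equal(got$sd, sd(x), tolerance = 1e-9)
  }
  # symmetry
  a <- summary_stat(3, 1, 10); b <- summary_stat(7, 2, 30)
  expect_equal(combine_arms(a, b)[1:3], combine_arms(b, a)[1:3])
})

test_that("summary-based Welch equals a raw-data Welch oracle", {
  set.seed(403)
  for (i in 1:100) {
    n1 <- sample(3:80, 1); n2 <- sample(3:300, 1)
    x <- sample_with_moments(n1, runif(1, -10, 90), runif(1, 0.3, 25))
    y <- sample_with_moments(n2, runif(1, -10, 90), runif(1, 0.3, 25))
    got <- welch_from_summaries(summary_stat(mean(x), sd(x), n1),
                                summary_stat(mean(y), sd(y), n2))
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Welch identity and degenerate cases", {
  same <- welch_from_summaries(summary_stat(5, 2, 30), summary_stat(5, 2, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$direction, "none")
  flat <- welch_from_summaries(summary_stat(5, 0, 30), summary_stat(5, 0, 30))
  expect_equal(flat$p_value, 1)
  expect_true(flat$degenerate)
  apart <- welch_from_summaries(summary_stat(6, 0, 30), summary_stat(5, 0, 30))
  expect_equal(apart$p_value, 0)
  expect_true(apart$degenerate)
  expect_identical(apart$direction, "higher")
  expect_error(welch_from_summaries(summary_stat(5, 1, 1), summary_stat(5, 1, 30)),
               "n >= 2")
})

test_that("Welch p-value decreases monotonically in mean separation", {
  ref <- summary_stat(50, 10, 500)
  deltas <- seq(0.5, 10, by = 0.5)
  ps <- vapply(deltas, function(d) {
    welch_from_summaries(summary_stat(50 + d, 8, 120), ref)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("chi-squared: hand case, symmetry, degenerate margins, oracle", {
  # [[20,10],[10,20]]: expected counts all 15, statistic 4 * 25/15 = 20/3
  got <- chi_squared_proportions(20, 30, 10, 30)
  expect_equal(got$statistic, 20 / 3)
  expect_identical(got$direction, "higher")
  # equal proportions
  eq <- chi_squared_proportions(20, 100, 200, 1000)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_identical(eq$direction, "none")
  # swapping groups keeps the statistic, flips the direction
  sw <- chi_squared_proportions(10, 30, 20, 30)
  expect_equal(sw$statistic, got$statistic)
  expect_identical(sw$direction, "lower")
  # zero margin is degenerate
  z <- chi_squared_proportions(0, 30, 0, 300)
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  # random tables against stats::chisq.test without correction
  set.seed(404)
  for (i in 1:25) {
    n1 <- sample(10:500, 1); n2 <- sample(10:3000, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    got <- chi_squared_proportions(x1, n1, x2, n2)
    ref <- suppressWarnings(chisq.test(
      matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE), correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})
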