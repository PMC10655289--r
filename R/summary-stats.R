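#' Construct a mean/SD/n summary statistic
#'
#' The common currency of the audit: every trial demographic report is
#' normalised to a mean, a standard deviation and a sample size before any
#' two-sample inference is run.  `source` records how the summary was
#' obtained, so that downstream verdicts can be traced back to a conversion.
#'
#' @param mean Sample mean, in the units of the parameter.
#' @param sd Sample standard deviation (>= 0).
#' @param n Sample size (positive integer).
#' @param source One of `"reported"`, `"from_median_range"`,
#'   `"from_median_iqr"`, `"from_five_number"`, `"combined_arms"`.
#' @return An object of class `summary_stat`: a list with elements `mean`,
#'   `sd`, `n`, `source`.
#' @export
#' @examples
#' summary_stat(55.1, 16.0, 2792)
summary_stat <- function(mean, sd, n,
                         source = c("reported", "from_median_range",
                                    "from_median_iqr", "from_five_number",
                                    "combined_arms")) {
  source <- match.arg(source)
  stopifnot(is.finite(mean), is.finite(sd), is.finite(n))
  if (sd < 0) stop("sd must be non-negative")
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n), source = source),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("summary_stat: mean %.4g (SD %.4g), n = %d [%s]\n",
              x$mean, x$sd, x$n, x$source))
  invisible(x)
}

#' Construct a quantile-based demographic report
#'
#' Represents a trial demographic reported as a median with an
#' interquartile range and/or a range, as many older trials do.  At least
#' one complete spread (both quartiles, or both extremes) must accompany
#' the median.
#'
#' @param median Reported median.
#' @param n Sample size (positive integer).
#' @param q1,q3 First and third quartiles (optional, supply both or neither).
#' @param min,max Sample minimum and maximum (optional, supply both or
#'   neither).
#' @return An object of class `quantile_report`.
#' @export
#' @examples
#' quantile_report(median = 10, n = 100, q1 = 8, q3 = 15)
quantile_report <- function(median, n, q1 = NA, q3 = NA, min = NA, max = NA) {
  has_iqr <- !is.na(q1) && !is.na(q3)
  has_range <- !is.na(min) && !is.na(max)
  if (xor(is.na(q1), is.na(q3))) stop("supply both q1 and q3 or neither")
  if (xor(is.na(min), is.na(max))) stop("supply both min and max or neither")
  if (!has_iqr && !has_range) {
    stop("a median alone cannot be converted: supply q1/q3 and/or min/max")
  }
  if (is.na(n) || n < 1 || n != round(n)) stop("n must be a positive integer")
  vals <- c(min, q1, median, q3, max)
  vals <- vals[!is.na(vals)]
  if (is.unsorted(vals)) {
    stop("quantiles must be ordered: min <= q1 <= median <= q3 <= max")
  }
  structure(list(median = as.numeric(median), q1 = as.numeric(q1),
                 q3 = as.numeric(q3), min = as.numeric(min),
                 max = as.numeric(max), n = as.integer(n)),
            class = "quantile_report")
}

#' Estimate a mean from a median and quantiles
#'
#' Location estimators for converting median-based trial reports to means:
#' `(a + 2m + b)/4` from a median and range, `(q1 + m + q3)/3` from a
#' median and IQR, and `(a + 2 q1 + 2 m + 2 q3 + b)/8` when all five
#' numbers are available.
#'
#' @param report A [quantile_report()].
#' @return Estimated mean (numeric scalar).
#' @seealso [sd_from_quantiles()]
#' @export
#' @examples
#' mean_from_quantiles(quantile_report(2, n = 50, min = 1, max = 9)) # 3.5
mean_from_quantiles <- function(report) {
  stopifnot(inherits(report, "quantile_report"))
  has_iqr <- !is.na(report$q1)
  has_range <- !is.na(report$min)
  if (has_iqr && has_range) {
    (report$min + 2 * report$q1 + 2 * report$median + 2 * report$q3 +
       report$max) / 8
  } else if (has_iqr) {
    (report$q1 + report$median + report$q3) / 3
  } else {
    (report$min + 2 * report$median + report$max) / 4
  }
}

#' Estimate a standard deviation from quantiles
#'
#' Normal-order-statistic spread estimators.  From a range,
#' `sd = (max - min) / (2 * qnorm((n - 0.375)/(n + 0.25)))`; from an IQR,
#' `sd = (q3 - q1) / (2 * qnorm((0.75 n - 0.125)/(n + 0.25)))`.  When both
#' spreads are present the IQR form is used (it is far less sensitive to
#' outlying extremes).  `method = "simple"` instead applies the familiar
#' rules of thumb `range/4` and `IQR/1.35`.
#'
#' @param report A [quantile_report()]; `n >= 2` required.
#' @param method `"wan"` (normal-order-statistic, default) or `"simple"`.
#' @return Estimated SD (numeric scalar, >= 0).
#' @export
#' @examples
#' sd_from_quantiles(quantile_report(15, n = 1e6, q1 = 10, q3 = 20))
sd_from_quantiles <- function(report, method = c("wan", "simple")) {
  stopifnot(inherits(report, "quantile_report"))
  method <- match.arg(method)
  n <- report$n
  if (n < 2) stop("sd estimation requires n >= 2")
  has_iqr <- !is.na(report$q1)
  if (has_iqr) {
    spread <- report$q3 - report$q1
    denom <- if (method == "wan") {
      2 * stats::qnorm((0.75 * n - 0.125) / (n + 0.25))
    } else 1.35
  } else {
    spread <- report$max - report$min
    denom <- if (method == "wan") {
      2 * stats::qnorm((n - 0.375) / (n + 0.25))
    } else 4
  }
  if (spread == 0) {
    warning("degenerate quantiles (zero spread): sd estimated as 0")
    return(0)
  }
  spread / denom
}

#' Pool two trial arms into a single summary
#'
#' Combines intervention and control arm summaries into one group using the
#' pooled-group formula: the combined mean is the size-weighted mean and the
#' combined SD folds in the between-arm mean difference, so that the result
#' equals the mean and SD of the concatenated raw samples.
#'
#' @param arm1,arm2 [summary_stat()] objects for the two arms.
#' @return A [summary_stat()] with `source = "combined_arms"`.
#' @export
#' @examples
#' combine_arms(summary_stat(10, 2, 50), summary_stat(12, 3, 70))
combine_arms <- function(arm1, arm2) {
  stopifnot(inherits(arm1, "summary_stat"), inherits(arm2, "summary_stat"))
  n1 <- arm1$n; n2 <- arm2$n
  if (n1 + n2 < 2) stop("combined sample size must be at least 2")
  m <- (n1 * arm1$mean + n2 * arm2$mean) / (n1 + n2)
  ss <- (n1 - 1) * arm1$sd^2 + (n2 - 1) * arm2$sd^2 +
    (n1 * n2 / (n1 + n2)) * (arm1$mean - arm2$mean)^2
  s <- sqrt(ss / (n1 + n2 - 1))
  summary_stat(m, s, n1 + n2, source = "combined_arms")
}

test_result <- function(statistic, df, p_value, direction, test,
                        degenerate = FALSE) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 direction = direction, test = test, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df %.4g, p %.4g, direction %s%s\n",
              x$test, x$statistic, x$df, x$p_value, x$direction,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance two-sample t-test computed directly from mean/SD/n
#' summaries, with Welch-Satterthwaite degrees of freedom and a two-sided
#' p-value.  `direction` is the sign of the trial-minus-reference
#' difference.  When both SDs are zero the test is degenerate: p = 1 if the
#' means agree, otherwise p = 0 with a degeneracy flag.
#'
#' @param trial,reference [summary_stat()] objects; both need `n >= 2`.
#' @param alpha Significance level carried through for convenience.
#' @return A `test_result` list: `statistic` (t), `df`, `p_value`,
#'   `direction` (`"higher"`, `"lower"`, `"none"`), `test = "welch_t"`.
#' @export
#' @examples
#' welch_from_summaries(summary_stat(65.4, 11.4, 482),
#'                      summary_stat(55.1, 16.0, 2792))
welch_from_summaries <- function(trial, reference, alpha = 0.05) {
  stopifnot(inherits(trial, "summary_stat"), inherits(reference, "summary_stat"))
  if (trial$n < 2 || reference$n < 2) stop("both groups need n >= 2")
  delta <- trial$mean - reference$mean
  v1 <- trial$sd^2 / trial$n
  v2 <- reference$sd^2 / reference$n
  if (v1 + v2 == 0) {
    if (delta == 0) {
      return(test_result(0, Inf, 1, "none", "welch_t", degenerate = TRUE))
    }
    return(test_result(sign(delta) * Inf, Inf, 0,
                       if (delta > 0) "higher" else "lower",
                       "welch_t", degenerate = TRUE))
  }
  tstat <- delta / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (trial$n - 1) + v2^2 / (reference$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  dir <- if (tstat > 0) "higher" else if (tstat < 0) "lower" else "none"
  test_result(tstat, df, p, dir, "welch_t")
}

#' Pearson chi-squared test for two proportions
#'
#' Chi-squared test on the 2x2 table of successes and failures in two
#' groups, without continuity correction (the reference group in this
#' audit is large, so the correction would be needless conservatism; set
#' `correct = TRUE` to apply it).  A table with an all-zero margin is
#' degenerate and returns p = 1 with a flag.
#'
#' @param trial_success,trial_n Successes and size of the trial group.
#' @param ref_success,ref_n Successes and size of the reference group.
#' @param alpha Significance level carried through for convenience.
#' @param correct Apply the Yates continuity correction.
#' @return A `test_result` list with `test = "chi_squared"`, `df = 1`,
#'   `direction` comparing the trial proportion with the reference.
#' @export
#' @examples
#' chi_squared_proportions(186, 482, 773, 2638)
chi_squared_proportions <- function(trial_success, trial_n,
                                    ref_success, ref_n,
                                    alpha = 0.05, correct = FALSE) {
  if (trial_success < 0 || trial_success > trial_n ||
      ref_success < 0 || ref_success > ref_n) {
    stop("successes must lie in [0, n]")
  }
  if (trial_n < 1 || ref_n < 1) stop("both groups need n >= 1")
  a <- trial_success; b <- trial_n - trial_success
  c <- ref_success;   d <- ref_n - ref_success
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  p1 <- a / trial_n; p2 <- c / ref_n
  dir <- if (p1 > p2) "higher" else if (p1 < p2) "lower" else "none"
  if (any(margins == 0)) {
    return(test_result(0, 1, 1, "none", "chi_squared", degenerate = TRUE))
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (stat == 0) dir <- "none"
  test_result(stat, 1, p, dir, "chi_squared")
}
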