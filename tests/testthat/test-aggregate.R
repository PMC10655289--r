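test_that("subgroup tallies partition the whole cohort", {
  tr <- bundled_trials()
  va <- verdicts_from_columns(tr)
  overall <- tally_mismatch(va, tr, "overall")
  for (g in c("specialty", "topic", "outcome", "size_split", "age_split")) {
    tg <- tally_mismatch(va, tr, g)
    expect_equal(sum(tg$params_reported), overall$params_reported)
    expect_equal(sum(tg$n_trials), overall$n_trials)
    expect_true(all(tg$params_statistical <= tg$params_reported))
    expect_true(all(tg$trials_any_statistical <= tg$n_trials))
  }
})

test_that("a mismatch-free trial tallies as zero", {
  tr <- make_trial_row(n = 500, age_mean = 55.1, age_sd = 16.0)
  tr$years_since_publication <- 1; tr$topic_group <- "other"
  tr$outcome <- "non_significant"
  va <- audit_trials(tr, bundled_reference())
  t0 <- tally_mismatch(va, tr, "overall")
  expect_equal(t0$trials_any_statistical, 0L)
  expect_equal(t0$n_trials, 1L)
})

test_that("subgroup contrasts match the chi-squared oracle", {
  ta <- data.frame(params_reported = 100, params_statistical = 50,
                   params_substantial = 10)
  tb <- data.frame(params_reported = 100, params_statistical = 50,
                   params_substantial = 90)
  same <- compare_subgroups(ta, tb, "params_statistical")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  diff <- compare_subgroups(ta, tb, "params_substantial")
  ref <- suppressWarnings(chisq.test(matrix(c(10, 90, 90, 10), 2, byrow = TRUE),
                                     correct = FALSE))
  expect_equal(diff$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_lt(diff$p_value, 1e-10)
})

test_that("the publication-age split reproduces the printed parameter counts", {
  tr <- bundled_trials()
  va <- verdicts_from_columns(tr)
  tg <- tally_mismatch(va, tr, "age_split")
  older <- tg[tg$label == "older", ]; newer <- tg[tg$label == "recent", ]
  # older trials: 73 of 86 parameters mismatched (84.9%); newer: 91 of 119 (76.5%)
  expect_equal(older$params_statistical, 73L)
  expect_equal(older$params_reported, 86L)
  expect_equal(newer$params_statistical, 91L)
  expect_equal(newer$params_reported, 119L)
  expect_gt(older$params_statistical / older$params_reported,
            newer$params_statistical / newer$params_reported)
  # the 2x2 chi-squared contrast on these counts is well-defined (the
  # originally reported p-value is not recoverable from the printed counts)
  res <- compare_subgroups(older, newer, "params_statistical")
  expect_true(is.finite(res$p_value))
  expect_equal(res$p_value,
               suppressWarnings(chisq.test(matrix(c(73, 13, 91, 28), 2,
                                                  byrow = TRUE),
                                           correct = FALSE))$p.value,
               tolerance = 1e-9)
})

test_that("yearly pooling follows the inverse-variance arithmetic", {
  one <- pool_by_year(2020, 42, 3)
  expect_equal(one$pooled_value, 42)
  expect_equal(one$n_trials, 1L)
  eq <- pool_by_year(c(2020, 2020), c(10, 20), c(2, 2))
  expect_equal(eq$pooled_value, 15)
  # SE ratio 1:2 means weight ratio 4:1
  ratio <- pool_by_year(c(2019, 2019), c(10, 20), c(4, 1))
  expect_equal(ratio$pooled_value, (4 * 10 + 1 * 20) / 5)
  expect_error(pool_by_year(2020, 5, -1), "positive")
})

test_that("equal weights reduce pooling to unweighted yearly means", {
  set.seed(601)
  year <- sample(2000:2005, 40, replace = TRUE)
  x <- rnorm(40)
  a <- pool_by_year(year, x, rep(2.5, 40))
  b <- vapply(sort(unique(year)), function(y) mean(x[year == y]), numeric(1))
  expect_equal(a$pooled_value, b, tolerance = 1e-12)
})

test_that("Spearman's rho handles ties, monotone maps and degenerate input", {
  expect_equal(spearman_rho(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spearman_rho(1:5, -(1:5)), -1)
  # brute-force: 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d = (0,1,1,0)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  set.seed(602)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_rho(x, y), spearman_rho(exp(x), y^3 + 5 * y))
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("ROC: separable, brute-force and tie cases", {
  perf <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), direction = ">")
  expect_equal(perf$auc, 1)
  mid <- roc_curve(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE), direction = ">")
  expect_equal(mid$auc, 0.75)  # brute force over the 4 positive/negative pairs
  tied <- roc_curve(c(1, 1, 2, 2), c(FALSE, TRUE, FALSE, TRUE), direction = ">")
  expect_equal(tied$auc, 0.5)  # ties earn half credit
  expect_error(roc_curve(1:4, c(TRUE, TRUE, TRUE, TRUE)), "both classes")
})

test_that("rank and trapezoid AUC agree on random instances", {
  set.seed(603)
  for (i in 1:50) {
    n <- sample(10:120, 1)
    score <- sample(rnorm(n), n)  # ties impossible
    if (i %% 2 == 0) score <- round(score, 1)  # force ties half the time
    label <- runif(n) < 0.4
    if (!any(label) || all(label)) next
    r <- roc_curve(score, label, direction = ">")
    expect_equal(r$auc, r$auc_trapezoid, tolerance = 1e-9)
  }
})

test_that("AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(604)
  for (i in 1:10) {
    n <- 60
    score <- round(rnorm(n), 1)
    label <- runif(n) < 0.5
    if (!any(label) || all(label)) next
    mine <- roc_curve(score, label, direction = ">")
    ref <- pROC::roc(response = label, predictor = score, quiet = TRUE,
                     direction = "<")  # pROC "<": controls below cases
    expect_equal(mine$auc, as.numeric(ref$auc), tolerance = 1e-9)
  }
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(605)
  r <- roc_curve(rnorm(4000), runif(4000) < 0.5, direction = ">")
  expect_lt(abs(r$auc - 0.5), 0.03)
})

test_that("temporal trends recover a known direction on pooled points", {
  # synthetic: age increases with calendar year
  set.seed(606)
  tr <- data.frame(trial_id = sprintf("T%02d", 1:30),
                   years_since_publication = rep(0:9, 3),
                   n_participants = 200,
                   age_mean = 60 - 0.5 * rep(0:9, 3) + rnorm(30, sd = 0.2),
                   age_sd = 12)
  tt <- temporal_trend(tr, "age")
  expect_gt(tt$rho, 0.9)
  expect_equal(tt$n_trials, 30)
  expect_equal(nrow(tt$points), 10)
})
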