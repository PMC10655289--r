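#' Subgroup tallies of mismatch
#'
#' Counts trials and parameters, statistically and substantially
#' mismatched, within subgroups of the trial table.  `size_split` divides
#' at the median trial size and `age_split` at the median years since
#' publication, with the `<= median` group labelled `small` / `recent`.
#'
#' @param audit A `mismatch_audit` from [audit_trials()] or
#'   [verdicts_from_columns()].
#' @param trials The trial data frame the audit was computed from.
#' @param grouping One of `"overall"`, `"specialty"`, `"topic"`,
#'   `"outcome"`, `"size_split"`, `"age_split"`.
#' @return Data frame with one row per subgroup: `grouping`, `label`,
#'   `n_trials`, `trials_any_statistical`, `params_reported`,
#'   `params_statistical`, `trials_any_substantial`, `params_substantial`.
#' @export
tally_mismatch <- function(audit, trials,
                           grouping = c("overall", "specialty", "topic",
                                        "outcome", "size_split", "age_split")) {
  grouping <- match.arg(grouping)
  need <- switch(grouping, topic = "topic_group", outcome = "outcome",
                 size_split = "n_participants",
                 age_split = "years_since_publication", NULL)
  if (!is.null(need) && !need %in% names(trials)) {
    stop("grouping '", grouping, "' needs column '", need, "'")
  }
  cols <- intersect(c("trial_id", "n_participants", "topic_group", "outcome",
                      "years_since_publication"), names(trials))
  tt <- merge(audit$trials, trials[, cols, drop = FALSE],
              by = "trial_id", sort = FALSE)
  lab <- switch(grouping,
    overall = rep("all", nrow(tt)),
    specialty = tt$specialty,
    topic = tt$topic_group,
    outcome = tt$outcome,
    size_split = ifelse(tt$n_participants <=
                          stats::median(tt$n_participants), "small", "large"),
    age_split = ifelse(tt$years_since_publication <=
                         stats::median(tt$years_since_publication),
                       "recent", "older"))
  tt$label <- lab
  pp <- merge(audit$parameters,
              tt[, c("trial_id", "label")], by = "trial_id", sort = FALSE)
  out <- do.call(rbind, lapply(sort(unique(lab)), function(l) {
    ti <- tt[tt$label == l, ]
    pi <- pp[pp$label == l, ]
    data.frame(grouping = grouping, label = l,
               n_trials = nrow(ti),
               trials_any_statistical = sum(ti$any_statistical),
               params_reported = nrow(pi),
               params_statistical = sum(pi$statistical),
               trials_any_substantial = sum(ti$any_substantial),
               params_substantial = sum(pi$substantial, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Chi-squared contrast between two subgroup tallies
#'
#' 2x2 Pearson chi-squared on mismatched versus matched parameter counts
#' in two subgroups.
#'
#' @param tally_a,tally_b Single rows of [tally_mismatch()] output.
#' @param basis `"params_statistical"` (default) or `"params_substantial"`.
#' @return A `test_result`.
#' @export
compare_subgroups <- function(tally_a, tally_b,
                              basis = c("params_statistical",
                                        "params_substantial")) {
  basis <- match.arg(basis)
  denom <- "params_reported"
  if (tally_a[[denom]] < 1 || tally_b[[denom]] < 1) {
    stop("both subgroups need at least one reported parameter")
  }
  chi_squared_proportions(tally_a[[basis]], tally_a[[denom]],
                          tally_b[[basis]], tally_b[[denom]])
}

#' Inverse-variance-weighted pooling by year
#'
#' Fixed-effect pooling of per-trial values within years: the pooled value
#' for a year is `sum(w * x) / sum(w)`.  A year containing one trial
#' returns that trial's value.
#'
#' @param year Integer year (or year bin) per trial.
#' @param value Per-trial value.
#' @param weight Per-trial weight (> 0); inverse-variance in the standard
#'   analysis.
#' @return Data frame sorted by year: `year`, `pooled_value`,
#'   `total_weight`, `n_trials`.
#' @export
pool_by_year <- function(year, value, weight = rep(1, length(value))) {
  stopifnot(length(year) == length(value), length(value) == length(weight))
  keep <- !is.na(value) & !is.na(year) & !is.na(weight)
  if (!any(keep)) stop("no non-missing values to pool")
  if (any(weight[keep] <= 0)) stop("weights must be positive")
  year <- year[keep]; value <- value[keep]; weight <- weight[keep]
  ys <- sort(unique(year))
  out <- data.frame(
    year = ys,
    pooled_value = vapply(ys, function(y) {
      w <- weight[year == y]; v <- value[year == y]
      sum(w * v) / sum(w)
    }, numeric(1)),
    total_weight = vapply(ys, function(y) sum(weight[year == y]), numeric(1)),
    n_trials = vapply(ys, function(y) sum(year == y), integer(1)))
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.  A constant input has no
#' rank ordering: `NA` is returned with a warning.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: Spearman's rho is undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Temporal trend of a pooled trial demographic
#'
#' The evidence-expiry analysis: trials are binned by whole years since
#' publication (nearest integer), the per-trial values are pooled within
#' each bin by inverse-variance weighting, and Spearman's rho is computed
#' between calendar time (the negated bin, so positive rho means the
#' demographic increases towards the present) and the pooled value.
#'
#' Weighting conventions, selectable and documented in the package
#' vignette: for continuous parameters `"inv_sd2"` (default) weights each
#' trial by the inverse of its reported variance `1/sd^2`, tracking the
#' typical enrolled patient; `"inv_se2"` weights by `n/sd^2`, the inverse
#' squared standard error.  ASA 3+ percentages are pooled as proportions
#' on the logit scale with fixed-effect inverse-variance weights
#' `n p (1 - p)` (`scale = "logit"`, default) -- the standard
#' meta-analytic pooling for proportions, which keeps near-0% and
#' near-100% trials from dominating -- or on the raw proportion scale with
#' weights `n / (p (1 - p))` (`scale = "raw"`).  Proportions of exactly 0
#' or 1 receive the continuity adjustment `(x + 0.5)/(n + 1)`.
#'
#' @param trials Trial data frame with `years_since_publication`,
#'   `n_participants` and the parameter summary columns.
#' @param parameter `"age"`, `"weight"`, `"bmi"` or `"asa"`.
#' @param weighting `"inv_sd2"` or `"inv_se2"` (continuous parameters).
#' @param scale `"logit"` or `"raw"` (ASA pooling scale).
#' @return List: `parameter`, `points` (pooled series with `year` oriented
#'   as calendar time relative to the newest bin), `rho`, `n_trials`.
#' @export
temporal_trend <- function(trials, parameter,
                           weighting = c("inv_sd2", "inv_se2"),
                           scale = c("logit", "raw")) {
  weighting <- match.arg(weighting)
  scale <- match.arg(scale)
  stopifnot(parameter %in% PARAMETERS)
  bin <- -round(trials$years_since_publication)  # calendar orientation
  if (parameter == "asa") {
    pct <- trials$asa_pct_3plus
    n <- trials$n_participants
    keep <- !is.na(pct) & !is.na(n)
    p <- pct[keep] / 100
    n <- n[keep]; bin <- bin[keep]
    adj <- p <= 0 | p >= 1
    p[adj] <- (p[adj] * n[adj] + 0.5) / (n[adj] + 1)
    if (scale == "logit") {
      pts <- pool_by_year(bin, log(p / (1 - p)), n * p * (1 - p))
      pts$pooled_value <- 100 * stats::plogis(pts$pooled_value)
    } else {
      pts <- pool_by_year(bin, 100 * p, n / (p * (1 - p)))
    }
  } else {
    m <- trials[[paste0(parameter, "_mean")]]
    s <- trials[[paste0(parameter, "_sd")]]
    n <- trials$n_participants
    keep <- !is.na(m) & !is.na(s) & s > 0 & !is.na(n)
    w <- switch(weighting,
                inv_sd2 = 1 / s[keep]^2,
                inv_se2 = n[keep] / s[keep]^2)
    pts <- pool_by_year(bin[keep], m[keep], w)
  }
  list(parameter = parameter, points = pts,
       rho = if (nrow(pts) >= 3) spearman_rho(pts$year, pts$pooled_value)
             else NA_real_,
       n_trials = sum(pts$n_trials))
}

#' ROC curve and AUC from a score and binary labels
#'
#' Builds the ROC curve over all distinct score thresholds and computes the
#' AUC two ways: the tie-corrected Mann-Whitney rank statistic (ties count
#' one half) and trapezoidal integration of the curve.  The two agree to
#' numerical precision by construction of the curve; both are returned.
#' `direction = "auto"` (default) orients the score so that AUC >= 0.5,
#' reporting which orientation was chosen, as ROC software conventionally
#' does; `">"` scores positives higher, `"<"` lower.
#'
#' @param score Numeric predictor.
#' @param label Logical (or 0/1) outcome; both classes must be present.
#' @return An object of class `roc_result`: `auc`, `auc_trapezoid`,
#'   `direction`, `thresholds`, `sensitivity`, `specificity`, `n_positive`,
#'   `n_negative`.
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
roc_curve <- function(score, label, direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- as.logical(label[keep])
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve")
  }
  mw_auc <- function(s) {
    r <- rank(s)  # average ranks handle ties (half credit)
    (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  a <- mw_auc(score)
  if (direction == "auto") {
    direction <- if (a >= 0.5) ">" else "<"
  }
  if (direction == "<") {
    score <- -score
    a <- 1 - a
  }
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(score[label] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(score[!label] < t), numeric(1))
  fpr <- 1 - spec
  auc_trap <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(auc = a, auc_trapezoid = auc_trap, direction = direction,
                 thresholds = thr, sensitivity = sens, specificity = spec,
                 n_positive = n_pos, n_negative = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (trapezoid %.4f), direction '%s', %d+/%d-\n",
              x$auc, x$auc_trapezoid, x$direction, x$n_positive, x$n_negative))
  invisible(x)
}

#' ROC of trial age predicting substantial mismatch
#'
#' Convenience wrapper: scores each trial by its years since publication
#' and labels it positive if the audit flagged any substantial mismatch.
#'
#' @param audit A `mismatch_audit`.
#' @param trials Trial data frame with `years_since_publication`.
#' @param direction Passed to [roc_curve()].
#' @return A `roc_result`.
#' @export
mismatch_roc <- function(audit, trials, direction = "auto") {
  tt <- merge(audit$trials,
              trials[, c("trial_id", "years_since_publication")],
              by = "trial_id", sort = FALSE)
  keep <- tt$n_reported > 0
  roc_curve(tt$years_since_publication[keep], tt$any_substantial[keep],
            direction = direction)
}
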