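#' Audit configuration
#'
#' Collects the tunable knobs of the audit in one validated object.
#'
#' @param alpha Two-sided significance level for statistical mismatch
#'   (default 0.05).
#' @param conversion SD estimator for median-based reports: `"wan"`
#'   (normal-order-statistic, default) or `"simple"` (range/4, IQR/1.35).
#' @param age_threshold_years,weight_threshold_kg Substantial-mismatch
#'   thresholds: a mean difference strictly greater than the threshold is
#'   substantial (default 10 of each).
#' @param bmi_breaks Strictly increasing BMI band cut-points; defaults to
#'   the WHO bands `c(18.5, 25, 30)`.  Bands are lower-inclusive.
#' @param include_asa_in_substantial Whether a statistically mismatched ASA
#'   distribution counts towards a trial's *any substantial mismatch* flag.
#'   ASA has no mean-difference rule, but a shifted comorbidity mix is a
#'   clinically substantial difference; the original audit tallies it this
#'   way (default `TRUE`).
#' @param chi_correct Apply the Yates continuity correction in the ASA
#'   chi-squared test (default `FALSE`; the reference denominator is large).
#' @return An object of class `audit_config`.
#' @export
audit_config <- function(alpha = 0.05,
                         conversion = c("wan", "simple"),
                         age_threshold_years = 10,
                         weight_threshold_kg = 10,
                         bmi_breaks = c(18.5, 25, 30),
                         include_asa_in_substantial = TRUE,
                         chi_correct = FALSE) {
  conversion <- match.arg(conversion)
  stopifnot(alpha > 0, alpha < 1,
            age_threshold_years > 0, weight_threshold_kg > 0,
            all(diff(bmi_breaks) > 0))
  structure(list(alpha = alpha, conversion = conversion,
                 age_threshold_years = age_threshold_years,
                 weight_threshold_kg = weight_threshold_kg,
                 bmi_breaks = bmi_breaks,
                 include_asa_in_substantial = include_asa_in_substantial,
                 chi_correct = chi_correct),
            class = "audit_config")
}

#' BMI band classification
#'
#' WHO-style bands, half-open and lower-inclusive, so a BMI of exactly 25.0
#' is overweight and 18.5 is normal.
#'
#' @param bmi Numeric vector of BMI values (> 0).
#' @param breaks Strictly increasing cut-points (default `c(18.5, 25, 30)`).
#' @return Character vector: `"underweight"`, `"normal"`, `"overweight"`,
#'   `"obese"`.
#' @export
#' @examples
#' bmi_band(c(18.5, 25, 29.9, 30))
bmi_band <- function(bmi, breaks = c(18.5, 25, 30)) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) stop("bmi must be positive")
  labels <- c("underweight", "normal", "overweight", "obese")
  labels[findInterval(bmi, breaks) + 1L]
}

#' Substantial-mismatch rule
#'
#' The clinical-relevance rule: a trial is substantially mismatched on age
#' if its mean differs from the reference mean by more than
#' `age_threshold_years` years (strictly), on weight by more than
#' `weight_threshold_kg` kg, and on BMI if the trial mean falls in a
#' different BMI band from the reference mean.  ASA has no substantial
#' rule: `NA` is returned.
#'
#' @param parameter `"age"`, `"weight"`, `"bmi"` or `"asa"`.
#' @param trial_mean,reference_mean The two means being compared.
#' @param config An [audit_config()].
#' @return `TRUE`/`FALSE`, or `NA` for ASA.
#' @export
#' @examples
#' classify_substantial("age", 65.4, 55.1)  # delta 10.3 > 10
classify_substantial <- function(parameter, trial_mean, reference_mean,
                                 config = audit_config()) {
  switch(parameter,
    age = abs(trial_mean - reference_mean) > config$age_threshold_years,
    weight = abs(trial_mean - reference_mean) > config$weight_threshold_kg,
    bmi = bmi_band(trial_mean, config$bmi_breaks) !=
      bmi_band(reference_mean, config$bmi_breaks),
    asa = NA,
    stop("unknown parameter: ", parameter))
}

#' Statistical-mismatch test for one parameter
#'
#' Continuous parameters are tested with [welch_from_summaries()]; the ASA
#' distribution with [chi_squared_proportions()] on the 2x2 table of ASA 3+
#' versus below.  Statistical mismatch means p < alpha.
#'
#' @param parameter `"age"`, `"weight"`, `"bmi"` or `"asa"`.
#' @param trial For continuous parameters a [summary_stat()]; for ASA a
#'   list with `pct_3plus` (0-100) and `n`.
#' @param reference A `reference_summary`.
#' @param config An [audit_config()].
#' @return List: `parameter`, `trial_value`, `reference_value`,
#'   `statistical` (logical), `direction`, `test` (a `test_result`),
#'   `source`.
#' @export
classify_statistical <- function(parameter, trial, reference,
                                 config = audit_config()) {
  if (parameter == "asa") {
    x <- round(trial$pct_3plus / 100 * trial$n)
    res <- chi_squared_proportions(x, trial$n,
                                   reference$asa_3plus_count,
                                   reference$asa_recorded_n,
                                   alpha = config$alpha,
                                   correct = config$chi_correct)
    tv <- trial$pct_3plus
    rv <- 100 * reference$asa_3plus_count / reference$asa_recorded_n
    src <- "reported"
  } else {
    ref_stat <- reference[[parameter]]
    if (is.null(ref_stat) || ref_stat$n < 2) {
      stop("reference has no usable ", parameter, " summary")
    }
    res <- welch_from_summaries(trial, ref_stat, alpha = config$alpha)
    tv <- trial$mean
    rv <- ref_stat$mean
    src <- trial$source
  }
  list(parameter = parameter, trial_value = tv, reference_value = rv,
       statistical = res$p_value < config$alpha,
       direction = res$direction, test = res, source = src)
}

#' Audit one trial against a reference set
#'
#' Normalises every reported demographic of the trial, runs the
#' statistical and substantial mismatch rules against the matched
#' reference, and bundles the verdicts with per-trial tallies.  The
#' mismatch fraction is the number of statistically mismatched parameters
#' over the number of parameters the trial usably reports.
#'
#' @param trial_row One-row data frame from [read_trials()].
#' @param summaries Named list of references ([reference_set()]), or a
#'   single `reference_summary` used for every specialty.
#' @param config An [audit_config()].
#' @return An object of class `trial_verdict`: `trial_id`, `verdicts`
#'   (list per parameter), `n_reported`, `n_statistical`,
#'   `mismatch_fraction`, `any_statistical`, `any_substantial`.
#' @export
audit_trial <- function(trial_row, summaries, config = audit_config()) {
  if (inherits(summaries, "reference_summary")) {
    reference <- summaries
  } else {
    reference <- match_reference(trial_row$specialty[1], summaries)
  }
  verdicts <- list()
  for (p in c("age", "weight", "bmi")) {
    stat <- normalise_report(trial_row, p, conversion = config$conversion)
    if (is.null(stat)) next
    v <- classify_statistical(p, stat, reference, config)
    v$substantial <- classify_substantial(p, v$trial_value,
                                          v$reference_value, config)
    verdicts[[p]] <- v
  }
  asa_pct <- if ("asa_pct_3plus" %in% names(trial_row))
    trial_row$asa_pct_3plus[1] else NA_real_
  if (!is.na(asa_pct)) {
    v <- classify_statistical("asa",
                              list(pct_3plus = asa_pct,
                                   n = trial_row$n_participants[1]),
                              reference, config)
    v$substantial <- NA
    verdicts$asa <- v
  }
  n_reported <- length(verdicts)
  n_stat <- sum(vapply(verdicts, `[[`, logical(1), "statistical"))
  subst <- vapply(verdicts, `[[`, logical(1), "substantial")
  any_subst <- any(subst, na.rm = TRUE)
  if (config$include_asa_in_substantial && !is.null(verdicts$asa)) {
    any_subst <- any_subst || verdicts$asa$statistical
  }
  structure(list(trial_id = trial_row$trial_id[1],
                 specialty = trial_row$specialty[1],
                 reference = reference$specialty,
                 verdicts = verdicts,
                 n_reported = n_reported,
                 n_statistical = n_stat,
                 mismatch_fraction = if (n_reported) n_stat / n_reported else NA,
                 any_statistical = n_stat > 0,
                 any_substantial = any_subst),
            class = "trial_verdict")
}

#' @export
print.trial_verdict <- function(x, ...) {
  cat(sprintf("trial_verdict %s [%s vs %s reference]\n",
              x$trial_id, x$specialty, x$reference))
  for (v in x$verdicts) {
    cat(sprintf("  %-6s %7.1f vs %5.1f  p=%-8.3g %-17s substantial: %s\n",
                v$parameter, v$trial_value, v$reference_value,
                v$test$p_value,
                if (v$statistical) paste0("MISMATCH (", v$direction, ")")
                else "match",
                if (is.na(v$substantial)) "n/a" else v$substantial))
  }
  cat(sprintf("  mismatch fraction %d/%d\n", x$n_statistical, x$n_reported))
  invisible(x)
}

#' Audit a table of trials
#'
#' Runs [audit_trial()] over every row and assembles two data frames: a
#' long per-parameter verdict table and a per-trial summary table.
#'
#' @param trials Trial data frame from [read_trials()].
#' @param summaries Reference set (or single `reference_summary`).
#' @param config An [audit_config()].
#' @return An object of class `mismatch_audit` with elements `parameters`
#'   (one row per trial-parameter verdict), `trials` (one row per trial)
#'   and `config`.
#' @export
audit_trials <- function(trials, summaries, config = audit_config()) {
  per_trial <- lapply(seq_len(nrow(trials)), function(i) {
    audit_trial(trials[i, , drop = FALSE], summaries, config)
  })
  params <- do.call(rbind, lapply(per_trial, function(tv) {
    if (!length(tv$verdicts)) return(NULL)
    do.call(rbind, lapply(tv$verdicts, function(v) {
      data.frame(trial_id = tv$trial_id, parameter = v$parameter,
                 trial_value = v$trial_value,
                 reference_value = v$reference_value,
                 statistic = v$test$statistic, df = v$test$df,
                 p_value = v$test$p_value, statistical = v$statistical,
                 direction = v$direction, substantial = v$substantial,
                 source = v$source, stringsAsFactors = FALSE)
    }))
  }))
  rownames(params) <- NULL
  trial_tab <- do.call(rbind, lapply(per_trial, function(tv) {
    data.frame(trial_id = tv$trial_id, specialty = tv$specialty,
               n_reported = tv$n_reported, n_statistical = tv$n_statistical,
               mismatch_fraction = tv$mismatch_fraction,
               any_statistical = tv$any_statistical,
               any_substantial = tv$any_substantial,
               stringsAsFactors = FALSE)
  }))
  structure(list(parameters = params, trials = trial_tab, config = config),
            class = "mismatch_audit")
}

#' @export
print.mismatch_audit <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("mismatch_audit: %d trials, %d parameter verdicts\n",
              n, nrow(x$parameters)))
  cat(sprintf("  any statistical mismatch: %d/%d (%.1f%%)\n",
              sum(x$trials$any_statistical), n,
              100 * mean(x$trials$any_statistical)))
  cat(sprintf("  any substantial mismatch: %d/%d (%.1f%%)\n",
              sum(x$trials$any_substantial), n,
              100 * mean(x$trials$any_substantial)))
  invisible(x)
}

#' Reconstruct an audit object from printed verdict columns
#'
#' Trial extractions sometimes carry the original audit's printed verdicts
#' (columns `stat_age` ... `stat_asa` with values `yes_higher`,
#' `yes_lower`, `no`, `no_higher`, `no_lower`, and `subst_age` ...
#' `subst_bmi` with `yes`/`no`; empty = parameter not reported).  This
#' builds the same shape of object as [audit_trials()] from those columns
#' alone, so that tallies and ROC labels can be computed without
#' re-deriving verdicts -- the regression path when the original
#' per-specialty reference moments are not available.
#'
#' @param trials Trial data frame with verdict columns.
#' @param include_asa_in_substantial As in [audit_config()].
#' @return A `mismatch_audit` (with empty test-statistic fields).
#' @export
verdicts_from_columns <- function(trials, include_asa_in_substantial = TRUE) {
  needed <- c(paste0("stat_", PARAMETERS), paste0("subst_", c("age", "weight", "bmi")))
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks printed-verdict columns: ",
         paste(missing_cols, collapse = ", "))
  }
  rows <- list(); trows <- list()
  for (i in seq_len(nrow(trials))) {
    r <- trials[i, ]
    n_rep <- 0L; n_stat <- 0L; any_sub <- FALSE
    for (p in PARAMETERS) {
      sv <- r[[paste0("stat_", p)]]
      if (is.na(sv) || sv == "") next
      n_rep <- n_rep + 1L
      stat <- startsWith(sv, "yes")
      n_stat <- n_stat + stat
      dirn <- if (endsWith(sv, "higher")) "higher"
              else if (endsWith(sv, "lower")) "lower" else "none"
      sub <- if (p == "asa") NA else {
        sb <- r[[paste0("subst_", p)]]
        if (is.na(sb) || sb == "") NA else identical(sb, "yes")
      }
      if (isTRUE(sub)) any_sub <- TRUE
      if (p == "asa" && include_asa_in_substantial && stat) any_sub <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = r$trial_id, parameter = p,
        trial_value = NA_real_, reference_value = NA_real_,
        statistic = NA_real_, df = NA_real_, p_value = NA_real_,
        statistical = stat, direction = dirn, substantial = sub,
        source = "printed", stringsAsFactors = FALSE)
    }
    trows[[i]] <- data.frame(
      trial_id = r$trial_id, specialty = r$specialty,
      n_reported = n_rep, n_statistical = n_stat,
      mismatch_fraction = if (n_rep) n_stat / n_rep else NA_real_,
      any_statistical = n_stat > 0, any_substantial = any_sub,
      stringsAsFactors = FALSE)
  }
  structure(list(parameters = do.call(rbind, rows),
                 trials = do.call(rbind, trows),
                 config = audit_config(
                   include_asa_in_substantial = include_asa_in_substantial)),
            class = "mismatch_audit")
}
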