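PARAMETERS <- c("age", "weight", "bmi", "asa")
TOPIC_GROUPS <- c("ileus", "thromboprophylaxis", "fluid_therapy_gdt",
                  "analgesia", "transfusion_iron", "nutrition", "antibiotics",
                  "antiemetics", "bowel_prep", "other")

trial_numeric_cols <- function() {
  stems <- c("age", "weight", "bmi")
  c("publication_year", "years_since_publication", "n_participants",
    "n_centres",
    paste0(rep(stems, each = 7),
           c("_mean", "_sd", "_median", "_q1", "_q3", "_min", "_max")),
    "asa_pct_3plus")
}

#' Read a trial-extraction table
#'
#' Reads one row per trial from a CSV in the extraction schema: metadata
#' columns (`trial_id`, `publication_year`, `years_since_publication`,
#' `topic`, `specialty`, `outcome`, `n_participants`, ...) plus, for each of
#' age, weight and BMI, any of `<param>_mean`/`_sd`/`_median`/`_q1`/`_q3`/
#' `_min`/`_max`, and `asa_pct_3plus`.  Optional printed-verdict columns
#' (`stat_age` ... `subst_bmi`) are carried through untouched for
#' regression tallies.  Empty cells are missing values.
#'
#' Schema violations (missing required columns) are an error.  Rows that
#' break record invariants (n < 2, q1 > q3, negative SD, unknown
#' specialty) are dropped with a warning giving line numbers and reasons.
#'
#' @param path Path to the trial CSV.
#' @return Data frame of validated trial records.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "specialty", "n_participants")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trial CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("trial CSV contains no rows")
  for (col in intersect(trial_numeric_cols(), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  problems <- character()
  flag <- function(rows, why) {
    if (any(rows)) problems <<- c(problems, sprintf(
      "line %d: %s", which(rows) + 1L, why))
    rows
  }
  bad <- flag(is.na(df$n_participants) | df$n_participants < 2,
              "n_participants must be >= 2")
  bad <- bad | flag(!(df$specialty %in% c(SPECIALTIES, "mixed")),
                    "unknown specialty")
  for (p in c("age", "weight", "bmi")) {
    q1 <- df[[paste0(p, "_q1")]]; q3 <- df[[paste0(p, "_q3")]]
    if (!is.null(q1) && !is.null(q3)) {
      bad <- bad | flag(!is.na(q1) & !is.na(q3) & q1 > q3,
                        paste0(p, "_q1 exceeds ", p, "_q3"))
    }
    sd <- df[[paste0(p, "_sd")]]
    if (!is.null(sd)) bad <- bad | flag(!is.na(sd) & sd < 0,
                                        paste0(p, "_sd negative"))
  }
  if (!is.null(df$asa_pct_3plus)) {
    bad <- bad | flag(!is.na(df$asa_pct_3plus) &
                        (df$asa_pct_3plus < 0 | df$asa_pct_3plus > 100),
                      "asa_pct_3plus outside [0, 100]")
  }
  if (any(bad)) {
    warning("rejected ", sum(bad), " trial row(s):\n  ",
            paste(problems, collapse = "\n  "))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid trial rows after validation")
  df
}

#' The bundled multicentre-trial extraction
#'
#' An extraction of 106 multicentre RCTs of perioperative interventions in
#' major abdominal surgery (publication years 1987-2022, 44,499
#' participants), with per-trial demographic summaries, specialty, topic
#' and printed mismatch-verdict columns from the original audit against a
#' London tertiary-centre comparator cohort.
#'
#' @return Data frame of 106 trial records.
#' @seealso [bundled_reference()] for the matching comparator summary.
#' @export
#' @examples
#' nrow(bundled_trials())
bundled_trials <- function() {
  read_trials(system.file("extdata", "abdominal_trials.csv",
                          package = "rctmatch", mustWork = TRUE))
}

#' The bundled comparator-cohort summary
#'
#' Overall summary of the real-world comparator cohort for the bundled
#' audit: 2792 adults undergoing major abdominal surgery at a London
#' tertiary referral centre over one year (September 2021 to September
#' 2022); mean (SD) age 55.1 (16.0) years, weight 77.8 (17.8) kg, BMI 27.4
#' (5.6); 773 of the 2638 patients with a recorded ASA grade (29.3%) were
#' ASA 3 or higher.  Only the overall moments are published, so
#' recomputation of verdicts against this reference is exact for
#' mixed-specialty trials only.
#'
#' @return A `reference_summary`.
#' @export
bundled_reference <- function() {
  reference_from_moments(2792, 55.1, 16.0, 77.8, 17.8, 27.4, 5.6,
                         asa_3plus_count = 773, asa_recorded_n = 2638)
}

#' Normalise one demographic report to mean/SD/n
#'
#' Dispatches on what the trial reported: a mean/SD pair is passed through;
#' a median with IQR and/or range goes through [mean_from_quantiles()] and
#' [sd_from_quantiles()].  A median without any spread, or a mean without
#' an SD, cannot be used for inference: `NULL` is returned with a warning
#' and the parameter is excluded from the audit denominator.
#'
#' @param trial_row One-row data frame (a row of [read_trials()] output).
#' @param parameter `"age"`, `"weight"` or `"bmi"`.
#' @param conversion SD estimator passed to [sd_from_quantiles()].
#' @return A [summary_stat()], or `NULL` if the report is absent or
#'   unusable.
#' @export
normalise_report <- function(trial_row, parameter,
                             conversion = c("wan", "simple")) {
  conversion <- match.arg(conversion)
  g <- function(suffix) {
    col <- paste0(parameter, suffix)
    if (col %in% names(trial_row)) trial_row[[col]][1] else NA_real_
  }
  n <- trial_row$n_participants[1]
  m <- g("_mean"); s <- g("_sd")
  if (!is.na(m) && !is.na(s)) return(summary_stat(m, s, n))
  med <- g("_median")
  if (!is.na(med)) {
    rep <- tryCatch(
      quantile_report(med, n, q1 = g("_q1"), q3 = g("_q3"),
                      min = g("_min"), max = g("_max")),
      error = function(e) NULL)
    if (is.null(rep)) {
      warning(sprintf("%s: %s reported as a median without usable spread; excluded",
                      trial_row$trial_id[1], parameter))
      return(NULL)
    }
    src <- if (!is.na(rep$q1) && !is.na(rep$min)) "from_five_number"
           else if (!is.na(rep$q1)) "from_median_iqr" else "from_median_range"
    return(summary_stat(mean_from_quantiles(rep),
                        sd_from_quantiles(rep, method = conversion),
                        n, source = src))
  }
  if (!is.na(m) && is.na(s)) {
    warning(sprintf("%s: %s mean reported without SD; excluded",
                    trial_row$trial_id[1], parameter))
  }
  NULL
}
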