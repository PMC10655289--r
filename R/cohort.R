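SPECIALTIES <- c("colorectal", "hepatobiliary", "upper_gi",
                 "gynaecology", "urology", "vascular")

#' Read a patient-level reference cohort
#'
#' Reads a CSV with columns `patient_id`, `age`, `weight_kg`, `bmi`, `asa`,
#' `specialty` (empty cell = missing; header required).  Rows violating the
#' record invariants (age under 18, ASA outside 1-5, unknown specialty)
#' are dropped with a warning naming the offending lines.
#'
#' @param path Path to the cohort CSV.
#' @return A data frame of validated patient records.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "age", "weight_kg", "bmi", "asa", "specialty")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("cohort CSV contains no rows")
  for (col in c("age", "weight_kg", "bmi", "asa")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad <- which(is.na(df$age) | df$age < 18 |
                 !(df$specialty %in% SPECIALTIES) |
                 (!is.na(df$asa) & !(df$asa %in% 1:5)) |
                 (!is.na(df$weight_kg) & df$weight_kg <= 0) |
                 (!is.na(df$bmi) & df$bmi <= 0))
  if (length(bad)) {
    warning(sprintf("dropped %d invalid cohort row(s) at line(s): %s",
                    length(bad),
                    paste(utils::head(bad + 1L, 10), collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid cohort rows after validation")
  df
}

#' Summarise a patient cohort as a reference
#'
#' Computes per-parameter mean/SD/n (over non-missing values, so each
#' parameter carries its own denominator) and ASA 3+ counts over patients
#' with a recorded ASA grade, for the whole cohort or one surgical
#' specialty.
#'
#' @param patients Patient data frame as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param specialty `"overall"` (default) or one of the surgical
#'   specialties present in the cohort.
#' @return An object of class `reference_summary`: `specialty`, `n`,
#'   `age`/`weight`/`bmi` ([summary_stat()] objects), `asa_3plus_count`,
#'   `asa_recorded_n`.
#' @export
summarize_cohort <- function(patients, specialty = "overall") {
  stopifnot(is.data.frame(patients))
  if (specialty != "overall") {
    patients <- patients[patients$specialty == specialty, , drop = FALSE]
    if (nrow(patients) == 0) {
      stop("no patients in cohort for specialty '", specialty, "'")
    }
  }
  stat_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 1) return(NULL)
    summary_stat(mean(x), if (length(x) > 1) stats::sd(x) else 0, length(x))
  }
  asa <- patients$asa[!is.na(patients$asa)]
  structure(list(specialty = specialty,
                 n = nrow(patients),
                 age = stat_of(patients$age),
                 weight = stat_of(patients$weight_kg),
                 bmi = stat_of(patients$bmi),
                 asa_3plus_count = sum(asa >= 3),
                 asa_recorded_n = length(asa)),
            class = "reference_summary")
}

#' @export
print.reference_summary <- function(x, ...) {
  fmt <- function(s) if (is.null(s)) "-" else
    sprintf("%.1f (%.1f), n=%d", s$mean, s$sd, s$n)
  cat(sprintf("reference_summary [%s], n = %d\n", x$specialty, x$n))
  cat("  age:    ", fmt(x$age), "\n")
  cat("  weight: ", fmt(x$weight), "\n")
  cat("  bmi:    ", fmt(x$bmi), "\n")
  cat(sprintf("  ASA 3+: %d / %d (%.1f%%)\n", x$asa_3plus_count,
              x$asa_recorded_n,
              100 * x$asa_3plus_count / max(1, x$asa_recorded_n)))
  invisible(x)
}

#' Build a reference summary from published moments
#'
#' When only the printed summary of a comparator cohort is available (as is
#' typical for an external audit), construct the reference directly from
#' its moments instead of from patient-level records.
#'
#' @param n Total cohort size.
#' @param age_mean,age_sd,weight_mean,weight_sd,bmi_mean,bmi_sd Moments.
#' @param asa_3plus_count Patients graded ASA 3 or higher.
#' @param asa_recorded_n Patients with any recorded ASA grade.
#' @param specialty Label for the summary (default `"overall"`).
#' @return A `reference_summary`.
#' @export
#' @examples
#' reference_from_moments(2792, 55.1, 16.0, 77.8, 17.8, 27.4, 5.6, 773, 2638)
reference_from_moments <- function(n, age_mean, age_sd, weight_mean, weight_sd,
                                   bmi_mean, bmi_sd, asa_3plus_count,
                                   asa_recorded_n, specialty = "overall") {
  stopifnot(asa_3plus_count <= asa_recorded_n, asa_recorded_n <= n)
  structure(list(specialty = specialty, n = as.integer(n),
                 age = summary_stat(age_mean, age_sd, n),
                 weight = summary_stat(weight_mean, weight_sd, n),
                 bmi = summary_stat(bmi_mean, bmi_sd, n),
                 asa_3plus_count = as.integer(asa_3plus_count),
                 asa_recorded_n = as.integer(asa_recorded_n)),
            class = "reference_summary")
}

#' Reference summaries for every specialty plus overall
#'
#' @param patients Patient data frame.
#' @return Named list of `reference_summary` objects: `overall` plus one
#'   per specialty present in the cohort.
#' @export
reference_set <- function(patients) {
  specs <- sort(unique(patients$specialty))
  out <- c(list(overall = summarize_cohort(patients, "overall")),
           stats::setNames(lapply(specs, summarize_cohort, patients = patients),
                           specs))
  out
}

#' Select the matched reference for a trial
#'
#' Mixed-specialty trials are compared with the whole cohort; single-
#' specialty trials with the same-specialty subset.  A specialty absent
#' from the cohort is an error, never a silent fallback to overall.
#'
#' @param trial_specialty Trial specialty string, or `"mixed"`.
#' @param summaries Named list from [reference_set()], which must contain
#'   `overall`.
#' @return The matched `reference_summary`.
#' @export
match_reference <- function(trial_specialty, summaries) {
  stopifnot("overall" %in% names(summaries))
  if (trial_specialty %in% c("mixed", "overall")) {
    return(summaries$overall)
  }
  if (!trial_specialty %in% names(summaries)) {
    stop("specialty '", trial_specialty,
         "' is not represented in the reference cohort")
  }
  summaries[[trial_specialty]]
}
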