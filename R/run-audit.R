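#' Run a full mismatch audit and write its report bundle
#'
#' Composes the whole pipeline: read (or accept) the trial table and
#' patient cohort, build specialty reference summaries, audit every trial,
#' tally subgroups, fit the temporal trends and the ROC of trial age, and
#' write the results as CSV files plus a short human-readable summary.
#'
#' Files written to `out_dir`: `verdicts.csv` (per trial-parameter),
#' `trial_summary.csv` (per trial), `subgroups.csv` (tallies over every
#' grouping), `temporal_<parameter>.csv` (pooled yearly series) and
#' `roc_points.csv`, plus `summary.txt`.
#'
#' @param trials Trial data frame or path to a trial CSV.
#' @param cohort Patient data frame, path to a cohort CSV, or a
#'   `reference_summary`/named list of them when only summary moments are
#'   available (single-summary mode audits every trial against it).
#' @param config An [audit_config()].
#' @param out_dir Output directory, created if needed; `NULL` skips
#'   writing.
#' @return Invisibly, a list: `audit`, `tallies`, `trends`, `roc`,
#'   `summary_lines`.
#' @export
run_audit <- function(trials, cohort, config = audit_config(),
                      out_dir = NULL) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  summaries <- if (is.data.frame(cohort)) reference_set(cohort) else cohort
  audit <- audit_trials(trials, summaries, config)
  groupings <- c("overall", "specialty", "outcome", "size_split", "age_split")
  if ("topic_group" %in% names(trials)) groupings <- c(groupings, "topic")
  tallies <- do.call(rbind, lapply(groupings, function(g) {
    tally_mismatch(audit, trials, g)
  }))
  trends <- lapply(stats::setNames(PARAMETERS, PARAMETERS), function(p) {
    tryCatch(temporal_trend(trials, p), error = function(e) NULL)
  })
  roc <- tryCatch(mismatch_roc(audit, trials), error = function(e) NULL)
  overall <- tallies[tallies$grouping == "overall", ]
  summary_lines <- c(
    sprintf("Trials audited: %d (%d demographic parameters)",
            overall$n_trials, overall$params_reported),
    sprintf("Any statistical mismatch: %d/%d trials (%.1f%%)",
            overall$trials_any_statistical, overall$n_trials,
            100 * overall$trials_any_statistical / overall$n_trials),
    sprintf("Any substantial mismatch: %d/%d trials (%.1f%%)",
            overall$trials_any_substantial, overall$n_trials,
            100 * overall$trials_any_substantial / overall$n_trials),
    sprintf("Parameters statistically mismatched: %d/%d (%.1f%%)",
            overall$params_statistical, overall$params_reported,
            100 * overall$params_statistical / max(1, overall$params_reported)),
    vapply(PARAMETERS, function(p) {
      tr <- trends[[p]]
      if (is.null(tr) || is.na(tr$rho)) {
        sprintf("Temporal trend %s: not estimable", p)
      } else {
        sprintf("Temporal trend %s: Spearman rho %.2f over %d pooled years",
                p, tr$rho, nrow(tr$points))
      }
    }, character(1)),
    if (!is.null(roc)) {
      sprintf("ROC (years since publication vs any substantial mismatch): AUC %.2f",
              roc$auc)
    } else "ROC: not estimable (single-class labels)")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) utils::write.csv(
      df, file.path(out_dir, f), row.names = FALSE)
    wr(audit$parameters, "verdicts.csv")
    wr(audit$trials, "trial_summary.csv")
    wr(tallies, "subgroups.csv")
    for (p in PARAMETERS) {
      if (!is.null(trends[[p]])) {
        wr(trends[[p]]$points, sprintf("temporal_%s.csv", p))
      }
    }
    if (!is.null(roc)) {
      wr(data.frame(threshold = roc$thresholds,
                    sensitivity = roc$sensitivity,
                    specificity = roc$specificity), "roc_points.csv")
    }
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }
  invisible(list(audit = audit, tallies = tallies, trends = trends,
                 roc = roc, summary_lines = summary_lines))
}
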