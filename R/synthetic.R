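#' Configuration for the synthetic reference cohort
#'
#' Defaults emulate a year of major abdominal surgery at a large tertiary
#' centre: 2792 adults split across six surgical specialties (urology
#' 27.7%, gynaecology 26.0%, colorectal 22.0%, with the remainder assigned
#' to hepatobiliary, upper GI and vascular), truncated-normal ages (>= 18
#' years) with specialty-specific means, a common BMI distribution, weight
#' derived as BMI x height^2, and an ordinal ASA grade driven by an
#' age-linked latent comorbidity score.  The default parameters are
#' calibrated so the overall cohort reproduces mean (SD) age 55.1 (16.0)
#' years, weight 77.8 (17.8) kg, BMI 27.4 (5.6) and 29.3% ASA 3+.
#'
#' @param n_patients Cohort size.
#' @param specialty_mix Named proportions summing to 1.
#' @param age_mean Named per-specialty mean ages (years).
#' @param age_sd Named per-specialty age SDs (years).
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param height_mean,height_sd Height distribution (m), used only to
#'   derive weight from BMI.
#' @param asa_link_slope Latent comorbidity score slope per year of age.
#' @param asa_thresholds Three increasing cut-points on the latent score
#'   separating ASA 1/2, 2/3 and 3/4.
#' @param asa_missing_rate Proportion of patients with no recorded ASA.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2792,
                          specialty_mix = c(colorectal = 0.220,
                                            hepatobiliary = 0.100,
                                            upper_gi = 0.080,
                                            gynaecology = 0.260,
                                            urology = 0.277,
                                            vascular = 0.063),
                          age_mean = c(colorectal = 57.8, hepatobiliary = 58,
                                       upper_gi = 63, gynaecology = 42.6,
                                       urology = 56, vascular = 70),
                          age_sd = c(colorectal = 15, hepatobiliary = 15,
                                     upper_gi = 14.5, gynaecology = 15,
                                     urology = 15.5, vascular = 12.5),
                          bmi_mean = 27.31, bmi_sd = 5.75,
                          height_mean = 1.6825, height_sd = 0.10,
                          asa_link_slope = 0.05,
                          asa_thresholds = c(-1.078, 0.712, 2.511),
                          asa_missing_rate = 0.0552,
                          seed = 20220901) {
  stopifnot(n_patients >= 1,
            abs(sum(specialty_mix) - 1) < 1e-9,
            all(specialty_mix >= 0), all(specialty_mix <= 1),
            all(names(specialty_mix) %in% SPECIALTIES),
            setequal(names(age_mean), names(specialty_mix)),
            setequal(names(age_sd), names(specialty_mix)),
            all(age_sd > 0), bmi_sd > 0, height_sd > 0,
            all(diff(asa_thresholds) > 0),
            asa_missing_rate >= 0, asa_missing_rate < 1)
  structure(list(n_patients = as.integer(n_patients),
                 specialty_mix = specialty_mix,
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 asa_link_slope = asa_link_slope,
                 asa_thresholds = asa_thresholds,
                 asa_missing_rate = asa_missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# truncated normal sampler (lower bound only), inverse-CDF so the draw
# count is deterministic
rtnorm_lower <- function(n, mean, sd, lower) {
  p_low <- stats::pnorm(lower, mean, sd)
  if (any(p_low > 0.999)) {
    stop("infeasible truncation: mean lies far below the lower bound")
  }
  u <- stats::runif(n, p_low, 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic patient-level reference cohort
#'
#' Draws a cohort under a [cohort_config()]: specialty labels from the
#' configured mix, ages from specialty-specific truncated normals (>= 18),
#' BMI from a truncated normal (> 13), height from a normal, weight =
#' BMI x height^2, and ASA from an age-linked latent score
#' `slope x (age - 55) + N(0,1)` cut at the configured thresholds, with
#' ASA missing completely at random at the configured rate.
#'
#' @param config A [cohort_config()].
#' @return Data frame in the cohort schema: `patient_id`, `age`,
#'   `weight_kg`, `bmi`, `asa`, `specialty`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 500))
#' summarize_cohort(cohort)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  specs <- names(config$specialty_mix)
  specialty <- sample(specs, n, replace = TRUE, prob = config$specialty_mix)
  age <- numeric(n)
  for (sp in specs) {
    idx <- specialty == sp
    if (!any(idx)) next
    age[idx] <- rtnorm_lower(sum(idx), config$age_mean[[sp]],
                             config$age_sd[[sp]], lower = 18)
  }
  bmi <- rtnorm_lower(n, config$bmi_mean, config$bmi_sd, lower = 13)
  height <- stats::rnorm(n, config$height_mean, config$height_sd)
  weight <- bmi * height^2
  latent <- config$asa_link_slope * (age - 55) + stats::rnorm(n)
  asa <- 1L + findInterval(latent, config$asa_thresholds)
  asa[stats::runif(n) < config$asa_missing_rate] <- NA_integer_
  data.frame(patient_id = sprintf("P%04d", seq_len(n)),
             age = age, weight_kg = weight, bmi = bmi, asa = asa,
             specialty = specialty, stringsAsFactors = FALSE)
}

#' Configuration for a synthetic trial set
#'
#' Describes a set of trials whose enrolled populations drift linearly
#' with publication year away from a present-day base population, so that
#' the temporal stages of the audit can be tested against a known ground
#' truth.  Trial sizes are log-normal with a median of about 253
#' participants and IQR roughly 121-489, matching typical multicentre
#' perioperative trials.  Per-parameter reporting rates default to the
#' rates observed in the bundled extraction (age 97.2%, weight 27.4%, BMI
#' 46.2%, ASA 23.5%).  Negative drifts mean older trials enrolled younger,
#' lighter, leaner and less comorbid participants.
#'
#' @param n_trials Number of trials.
#' @param year_range Integer range of publication years; the upper end is
#'   the zero-drift anchor (and the audit date for computing years since
#'   publication).
#' @param size_meanlog,size_sdlog Log-normal trial-size parameters.
#' @param drift Named per-year drift: `age` (years/yr), `weight` (kg/yr),
#'   `bmi` ((kg/m^2)/yr), `asa3` (logit/yr), applied as
#'   `value(year) = base + drift x (year - anchor)`.
#' @param reporting_rates Named per-parameter reporting probabilities.
#' @param style_mix Proportions of report styles `mean_sd`, `median_iqr`,
#'   `median_range`.
#' @param seed Integer seed.
#' @return An object of class `trial_set_config`.
#' @export
trial_set_config <- function(n_trials = 100,
                             year_range = c(1987, 2022),
                             size_meanlog = log(253), size_sdlog = 1.04,
                             drift = c(age = 0.15, weight = 0.20,
                                       bmi = 0.05, asa3 = 0.03),
                             reporting_rates = c(age = 0.972, weight = 0.274,
                                                 bmi = 0.462, asa = 0.235),
                             style_mix = c(mean_sd = 0.7, median_iqr = 0.2,
                                           median_range = 0.1),
                             seed = 1L) {
  stopifnot(n_trials >= 1, length(year_range) == 2,
            year_range[1] <= year_range[2],
            all(reporting_rates >= 0), all(reporting_rates <= 1),
            setequal(names(reporting_rates), PARAMETERS),
            setequal(names(drift), c("age", "weight", "bmi", "asa3")),
            abs(sum(style_mix) - 1) < 1e-9,
            setequal(names(style_mix),
                     c("mean_sd", "median_iqr", "median_range")))
  structure(list(n_trials = as.integer(n_trials),
                 year_range = as.integer(year_range),
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 drift = drift, reporting_rates = reporting_rates,
                 style_mix = style_mix, seed = as.integer(seed)),
            class = "trial_set_config")
}

#' Generate a synthetic trial set with a ground-truth manifest
#'
#' For each trial: a publication year is drawn uniformly from the range, a
#' size from the log-normal, and participant-level samples of age, weight,
#' BMI and ASA 3+ status from the drifted population for that year.
#' Samples are summarised in the trial's report style (exact mean/SD, or
#' median with IQR or range) and masked according to the reporting rates.
#' The manifest retains every raw sample, the true population means and
#' the drift, so oracle tests can compare summary-based inference with
#' raw-data inference.
#'
#' @param config A [trial_set_config()].
#' @param base Named list of base (anchor-year) population parameters:
#'   `age_mean`, `age_sd`, `weight_mean`, `weight_sd`, `bmi_mean`,
#'   `bmi_sd`, `asa3_p`.  Defaults to the bundled comparator moments.
#' @return List with `trials` (data frame in the extraction schema) and
#'   `manifest` (`samples`: per-trial raw draws; `truth`: per-trial true
#'   population values; `config`, `base`).
#' @export
generate_trial_set <- function(config = trial_set_config(),
                               base = list(age_mean = 55.1, age_sd = 16.0,
                                           weight_mean = 77.8, weight_sd = 17.8,
                                           bmi_mean = 27.4, bmi_sd = 5.6,
                                           asa3_p = 0.293)) {
  stopifnot(inherits(config, "trial_set_config"))
  set.seed(config$seed)
  anchor <- config$year_range[2]
  nt <- config$n_trials
  year <- sample(seq(config$year_range[1], config$year_range[2]),
                 nt, replace = TRUE)
  size <- pmax(30L, pmin(4500L, round(stats::rlnorm(
    nt, config$size_meanlog, config$size_sdlog))))
  style <- sample(names(config$style_mix), nt, replace = TRUE,
                  prob = config$style_mix)
  rows <- vector("list", nt)
  samples <- vector("list", nt)
  truth <- vector("list", nt)
  for (i in seq_len(nt)) {
    dy <- year[i] - anchor
    mu_age <- base$age_mean + config$drift[["age"]] * dy
    mu_wgt <- base$weight_mean + config$drift[["weight"]] * dy
    mu_bmi <- base$bmi_mean + config$drift[["bmi"]] * dy
    p_asa <- stats::plogis(stats::qlogis(base$asa3_p) +
                             config$drift[["asa3"]] * dy)
    n <- size[i]
    smp <- list(age = rtnorm_lower(n, mu_age, base$age_sd, 18),
                weight = rtnorm_lower(n, mu_wgt, base$weight_sd, 30),
                bmi = rtnorm_lower(n, mu_bmi, base$bmi_sd, 13),
                asa3 = stats::runif(n) < p_asa)
    reported <- stats::runif(4) < config$reporting_rates[PARAMETERS]
    names(reported) <- PARAMETERS
    row <- data.frame(trial_id = sprintf("SYN%04d", i),
                      publication_year = year[i],
                      years_since_publication = as.numeric(anchor - year[i]),
                      specialty = "mixed", outcome = "non_significant",
                      topic_group = "other",
                      n_participants = n, stringsAsFactors = FALSE)
    for (p in c("age", "weight", "bmi")) {
      x <- smp[[p]]
      cols <- stats::setNames(
        rep(NA_real_, 7),
        paste0(p, c("_mean", "_sd", "_median", "_q1", "_q3", "_min", "_max")))
      if (reported[[p]]) {
        if (style[i] == "mean_sd") {
          cols[paste0(p, "_mean")] <- mean(x)
          cols[paste0(p, "_sd")] <- stats::sd(x)
        } else if (style[i] == "median_iqr") {
          q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
          cols[paste0(p, c("_q1", "_median", "_q3"))] <- q
        } else {
          cols[paste0(p, "_median")] <- stats::median(x)
          cols[paste0(p, "_min")] <- min(x)
          cols[paste0(p, "_max")] <- max(x)
        }
      }
      row <- cbind(row, as.data.frame(as.list(cols)))
    }
    row$asa_pct_3plus <- if (reported[["asa"]]) 100 * mean(smp$asa3) else NA_real_
    rows[[i]] <- row
    samples[[i]] <- smp
    truth[[i]] <- data.frame(trial_id = row$trial_id, year = year[i],
                             true_age_mean = mu_age, true_weight_mean = mu_wgt,
                             true_bmi_mean = mu_bmi, true_asa3_p = p_asa,
                             report_style = style[i],
                             stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  names(samples) <- trials$trial_id
  list(trials = trials,
       manifest = list(samples = samples, truth = do.call(rbind, truth),
                       config = config, base = base))
}
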