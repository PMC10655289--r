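# Construct a raw sample with exactly the requested mean and SD, so that
# summary-based inference can be checked against raw-data inference.
sample_with_moments <- function(n, mean, sd) {
  x <- stats::rnorm(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  x * sd + mean
}

# Exact mean and SD of a normal distribution truncated below at `lower`,
# for building a noise-free "generating population" reference.
trunc_moments <- function(mean, sd, lower) {
  z <- (lower - mean) / sd
  lambda <- stats::dnorm(z) / (1 - stats::pnorm(z))
  list(mean = mean + sd * lambda,
       sd = sd * sqrt(1 + z * lambda - lambda^2))
}

# One-row trial record in the extraction schema, for building small cases.
make_trial_row <- function(trial_id = "T1", specialty = "mixed", n = 100, ...) {
  cols <- list(...)
  df <- data.frame(trial_id = trial_id, specialty = specialty,
                   n_participants = n, stringsAsFactors = FALSE)
  for (nm in names(cols)) df[[nm]] <- cols[[nm]]
  df
}
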