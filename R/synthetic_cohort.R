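# Synthetic TDM cohorts with the statistical structure of the study
# population: 72 subjects, weights ~ truncated normal (mean 61.83, SD 11.82,
# range 40-92 kg), 18/72 on paroxetine, 1-3 trough samples per subject.

#' Design of a synthetic therapeutic-drug-monitoring cohort
#'
#' Defaults emulate the study cohort's published summary statistics.
#'
#' @param n_subjects Number of subjects (default 72).
#' @param weight_mean,weight_sd Moments of the untruncated weight normal
#'   (kg); defaults 61.83 and 11.82.
#' @param weight_bounds Truncation range in kg, default `c(40, 92)`.
#' @param par_fraction Proportion on paroxetine, default 18/72 = 0.25.
#' @param samples_range Integer range of trough samples per subject within
#'   `[1, 3]`; default `c(1, 3)`.
#' @param daily_doses Pool of total daily doses (mg/day) sampled uniformly
#'   per subject; default `c(5, 10, 15, 20)` — clinically plausible
#'   olanzapine maintenance doses (actual doses were not published).
#' @param frequency `"mixed"` (default; each subject is independently
#'   assigned once-daily or twice-daily dosing with equal probability —
#'   both regimens are in routine clinical use), `"bid"` (daily dose split
#'   evenly q12h) or `"qd"`.
#' @param dosing_days Days of dosing before the first observation window
#'   (default 10; the model's typical half-life is ~7 h, so this is far
#'   beyond accumulation).
#' @param trough_jitter_h Width of uniform jitter (h) subtracted from
#'   nominal trough times, emulating blood draws taken up to a few hours
#'   before the next dose; default 4. Set 0 for exact troughs — but note
#'   that with every sample at exactly one time after dose, CL/F and V/F
#'   are nearly unidentifiable (a flip-flop-like likelihood ridge), so
#'   exact-trough designs cannot support estimation.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_subjects = 72,
                          weight_mean = 61.83, weight_sd = 11.82,
                          weight_bounds = c(40, 92),
                          par_fraction = 18 / 72,
                          samples_range = c(1L, 3L),
                          daily_doses = c(5, 10, 15, 20),
                          frequency = c("mixed", "bid", "qd"),
                          dosing_days = 10,
                          trough_jitter_h = 4) {
  frequency <- match.arg(frequency)
  stopifnot(n_subjects >= 1,
            length(weight_bounds) == 2, all(weight_bounds > 0),
            weight_bounds[1] < weight_bounds[2],
            par_fraction >= 0, par_fraction <= 1,
            length(samples_range) == 2,
            samples_range[1] >= 1, samples_range[2] <= 3,
            samples_range[1] <= samples_range[2],
            all(daily_doses > 0), dosing_days >= 1,
            trough_jitter_h >= 0, trough_jitter_h < 12)
  if (weight_sd <= 0 ||
      (weight_mean < weight_bounds[1] - 3 * weight_sd) ||
      (weight_mean > weight_bounds[2] + 3 * weight_sd)) {
    stop("infeasible weight design: mean too far outside bounds for the SD",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_bounds = weight_bounds, par_fraction = par_fraction,
                 samples_range = as.integer(samples_range),
                 daily_doses = daily_doses, frequency = frequency,
                 dosing_days = dosing_days,
                 trough_jitter_h = trough_jitter_h),
            class = "cohort_design")
}

# Rejection sampler; the truncation window is ~1.8 SD wide either side of
# the mean, so acceptance is high and a loop is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Draw a synthetic cohort (covariates and dosing, no observations)
#'
#' Weights come from a truncated normal, paroxetine flags from a Bernoulli,
#' each subject receives a regular steady-state dosing schedule and 1-3
#' trough-timed observation slots (DV left `NA`). Fully reproducible from
#' `seed`.
#'
#' @param design A [cohort_design()] object.
#' @param seed Integer seed.
#' @return A list of `subject_record` objects (class `tdm_cohort`); each has
#'   `id`, `covariates`, `doses` (data frame `time`, `amount`) and `obs`
#'   (data frame `time`, `dv`).
#' @export
draw_cohort <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  n <- design$n_subjects
  wt <- rtruncnorm(n, design$weight_mean, design$weight_sd,
                   design$weight_bounds[1], design$weight_bounds[2])
  par <- stats::rbinom(n, 1, design$par_fraction)
  # sample.int on the index to avoid sample()'s scalar-x expansion
  obs_choices <- seq(design$samples_range[1], design$samples_range[2])
  n_obs <- obs_choices[sample.int(length(obs_choices), n, replace = TRUE)]
  daily <- design$daily_doses[sample.int(length(design$daily_doses), n,
                                         replace = TRUE)]
  freq <- switch(design$frequency,
                 mixed = sample(c("bid", "qd"), n, replace = TRUE),
                 rep(design$frequency, n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    tau <- if (freq[i] == "bid") 12 else 24
    n_per_day <- 24 / tau
    # dosing continues through the observation window so every trough is at
    # steady state
    total_days <- design$dosing_days + n_obs[i]
    doses <- dose_schedule(amount = daily[i] / n_per_day, interval = tau,
                           n_doses = total_days * n_per_day)
    # one trough per day after the run-in: immediately before a dose
    slot_dose <- design$dosing_days * n_per_day + (seq_len(n_obs[i]) - 1) * n_per_day + 1
    t_obs <- doses$time[slot_dose]
    if (design$trough_jitter_h > 0) {
      t_obs <- t_obs - stats::runif(n_obs[i], 0, design$trough_jitter_h)
    }
    subjects[[i]] <- structure(
      list(id = i,
           covariates = subject_covariates(weight = wt[i], par = par[i]),
           doses = doses,
           obs = data.frame(time = t_obs, dv = NA_real_)),
      class = "subject_record")
  }
  structure(subjects, class = "tdm_cohort")
}

#' @export
print.tdm_cohort <- function(x, ...) {
  n_obs <- sum(vapply(x, function(s) nrow(s$obs), integer(1)))
  cat(sprintf("TDM cohort: %d subjects, %d observations (%d on paroxetine)\n",
              length(x), n_obs,
              sum(vapply(x, function(s) s$covariates$par, numeric(1)))))
  invisible(x)
}

#' Simulate observed concentrations for a cohort
#'
#' Forward simulation of the full population model: one eta_CL draw per
#' subject, model predictions by dose superposition, then a combined
#' proportional + additive residual draw per observation. Observed values
#' are truncated at 0 (TDM reports cannot be negative); the untruncated
#' model remains the estimation contract.
#'
#' @param cohort A `tdm_cohort` from [draw_cohort()] (or any list of
#'   `subject_record`s with observation times set).
#' @param pop A [pop_params()] object (generating truth).
#' @param seed Integer seed.
#' @return The cohort with `obs$dv` filled; each subject additionally
#'   carries the simulated `eta_cl` and noise-free `obs$c_true` for
#'   reference.
#' @export
simulate_dataset <- function(cohort, pop, seed = 1L) {
  stopifnot(inherits(pop, "pop_params"))
  set.seed(seed)
  om <- omega_sd(pop)
  sv <- sigma_var(pop)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    eta <- if (om > 0) stats::rnorm(1, 0, om) else 0
    ind <- individualize(typical_params(s$covariates, pop), eta)
    c_true <- conc_superposition(s$doses, s$obs$time, ind)
    m <- length(c_true)
    eps1 <- if (sv[["prop"]] > 0) stats::rnorm(m, 0, sqrt(sv[["prop"]])) else rep(0, m)
    eps2 <- if (sv[["add"]] > 0) stats::rnorm(m, 0, sqrt(sv[["add"]])) else rep(0, m)
    dv <- apply_residual(c_true, eps1, eps2)
    s$obs$dv <- pmax(dv, 0)
    s$obs$c_true <- c_true
    s$eta_cl <- eta
    cohort[[i]] <- s
  }
  cohort
}
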