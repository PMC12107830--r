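# Independent oracles and small fixture builders used across the suite.

# Fixed-step RK4 integration of the two-state absorption/central system:
#   dA/dt = -ka * A          (gut, mg)
#   dC/dt = ka * A / V - ke * C   (central, mg/L)
# Returns concentrations in ng/mL at the requested times (sorted).
ode_conc_oracle <- function(dose, times, cl, v, ka, h = 0.002) {
  ke <- cl / v
  times <- sort(times)
  out <- numeric(length(times))
  A <- dose
  C <- 0
  t <- 0
  k <- 1
  deriv <- function(A, C) c(-ka * A, ka * A / v - ke * C)
  while (k <= length(times)) {
    step <- min(h, times[k] - t)
    if (step > 1e-12) {
      k1 <- deriv(A, C)
      k2 <- deriv(A + step / 2 * k1[1], C + step / 2 * k1[2])
      k3 <- deriv(A + step / 2 * k2[1], C + step / 2 * k2[2])
      k4 <- deriv(A + step * k3[1], C + step * k3[2])
      A <- A + step / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      C <- C + step / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      t <- t + step
    }
    if (abs(t - times[k]) < 1e-9) {
      out[k] <- 1000 * C
      k <- k + 1
    }
  }
  out
}

# Dense-grid marginal log-likelihood over eta for one subject; the
# brute-force stand-in for the adaptive quadrature (Simpson weights so the
# grid error is far below the 1e-6 comparison tolerance).
brute_marginal_loglik <- function(subject, pop, n = 10001, span = 6) {
  om <- olanzpk:::omega_sd(pop)
  etas <- seq(-span * om, span * om, length.out = n)
  typ <- typical_params(subject$covariates, pop)
  ll <- vapply(etas, function(e) {
    f <- conc_superposition(subject$doses, subject$obs$time,
                            individualize(typ, e))
    sum(stats::dnorm(subject$obs$dv, f, sqrt(residual_variance(f, pop)),
                     log = TRUE)) +
      stats::dnorm(e, 0, om, log = TRUE)
  }, numeric(1))
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1) / 3
  mx <- max(ll)
  mx + log(sum(w * exp(ll - mx)) * (etas[2] - etas[1]))
}

# One subject on a regular schedule with given observed values.
make_subject <- function(id = 1, weight = 70, par = 0, amount = 7.5,
                         interval = 12, n_doses = 22,
                         obs_time = c(252, 260), dv = NULL) {
  doses <- dose_schedule(amount, interval, n_doses)
  structure(list(id = id,
                 covariates = subject_covariates(weight = weight, par = par),
                 doses = doses,
                 obs = data.frame(time = obs_time,
                                  dv = dv %||% rep(NA_real_, length(obs_time)))),
            class = "subject_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moments of a truncated normal, for checking the weight generator against
# what it actually targets.
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  m <- mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
  v <- sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z -
                 ((stats::dnorm(a) - stats::dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}
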