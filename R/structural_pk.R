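# Closed-form one-compartment, first-order absorption kinetics.
#
# Unit convention throughout the package: dose in mg, volume in L,
# clearance in L/h, time in hours. Internal concentrations are mg/L;
# everything user-facing is reported in ng/mL (x 1000).

#' Individual pharmacokinetic parameters
#'
#' Container for one subject's apparent oral clearance (CL/F), apparent
#' volume of distribution (V/F) and first-order absorption rate constant.
#' Bioavailability is never separately identified from oral data alone, so
#' only the apparent ratios CL/F and V/F exist in this model.
#'
#' @param cl Apparent clearance CL/F (L/h), positive.
#' @param v Apparent volume V/F (L), positive.
#' @param ka Absorption rate constant (1/h), positive.
#' @return An object of class `individual_params` with fields `cl`, `v`,
#'   `ka` and the derived elimination constant `ke = cl / v`.
#' @examples
#' individual_params(cl = 19.6, v = 197, ka = 0.861)
#' @export
individual_params <- function(cl, v, ka) {
  stopifnot(is.numeric(cl), is.numeric(v), is.numeric(ka))
  if (any(!is.finite(cl)) || any(cl <= 0)) {
    stop("`cl` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("`v` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(ka)) || any(ka <= 0)) {
    stop("`ka` must be finite and positive", call. = FALSE)
  }
  structure(list(cl = cl, v = v, ka = ka, ke = cl / v),
            class = "individual_params")
}

#' @export
print.individual_params <- function(x, ...) {
  cat(sprintf("Individual PK parameters: CL/F = %.4g L/h, V/F = %.4g L, Ka = %.4g 1/h (ke = %.4g 1/h)\n",
              x$cl[1], x$v[1], x$ka[1], x$ke[1]))
  invisible(x)
}

# Relative threshold below which the ka == ke degenerate branch is used;
# avoids catastrophic cancellation in ka / (ka - ke).
.KA_KE_REL_TOL <- 1e-8

#' Concentration after a single oral dose
#'
#' Evaluates the one-compartment first-order absorption solution
#' \deqn{C(t) = 1000 \frac{D}{V} \frac{K_a}{K_a - k_e}
#'       \left(e^{-k_e t} - e^{-K_a t}\right), \quad k_e = CL/V,}
#' with the analytic limit \eqn{C(t) = 1000 (D/V) k_e t e^{-k_e t}} when
#' \eqn{|K_a - k_e| < 10^{-8} K_a}. The factor 1000 converts mg/L to ng/mL.
#'
#' @param dose Dose amount (mg), positive scalar.
#' @param t Time since the dose (h), non-negative; may be a vector.
#' @param params An [individual_params()] object (fields may be vectors
#'   conformable with `t`).
#' @return Concentration(s) in ng/mL; 0 at `t = 0`.
#' @examples
#' p <- individual_params(19.6, 197, 0.861)
#' conc_single_dose(14, 12, p)
#' @export
conc_single_dose <- function(dose, t, params) {
  if (!inherits(params, "individual_params")) {
    stop("`params` must be an `individual_params` object", call. = FALSE)
  }
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("`dose` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative", call. = FALSE)
  }
  .conc_single(dose, t, params$cl, params$v, params$ka)
}

# Vectorised core, no class dispatch; reused by superposition and by the
# estimation layer where cl varies across subjects.
.conc_single <- function(dose, t, cl, v, ka) {
  ke <- cl / v
  degenerate <- abs(ka - ke) < .KA_KE_REL_TOL * ka
  out <- 1000 * (dose / v) * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  if (any(degenerate)) {
    # recycle the mask to the broadcast shape before patching in the limit
    lim <- 1000 * (dose / v) * ke * t * exp(-ke * t) + 0 * out
    deg <- rep_len(degenerate, length(out))
    out[deg] <- lim[deg]
  }
  out
}

#' Concentration under a schedule of oral doses
#'
#' Linear superposition of [conc_single_dose()] terms: each dose given at or
#' before the query time contributes its single-dose curve shifted to its
#' dosing time; later doses contribute nothing.
#'
#' @param schedule A data frame with columns `time` (h since the first dose,
#'   non-decreasing, non-negative) and `amount` (mg, positive).
#' @param t Query time(s) in hours, non-negative.
#' @param params An [individual_params()] object.
#' @return Concentration(s) in ng/mL, one per element of `t`.
#' @examples
#' p <- individual_params(19.6, 197, 0.861)
#' sched <- dose_schedule(amount = 14, interval = 12, n_doses = 28)
#' conc_superposition(sched, 336, p)
#' @export
conc_superposition <- function(schedule, t, params) {
  schedule <- validate_schedule(schedule)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative", call. = FALSE)
  }
  dt <- outer(t, schedule$time, `-`)      # rows: query times, cols: doses
  active <- dt > 0
  dt[!active] <- 0
  amt <- matrix(schedule$amount, nrow = length(t), ncol = nrow(schedule),
                byrow = TRUE)
  contrib <- .conc_single(amt, dt, params$cl, params$v, params$ka)
  contrib[!active] <- 0
  rowSums(contrib)
}

#' Build a regular multiple-dose schedule
#'
#' @param amount Dose amount per administration (mg).
#' @param interval Dosing interval tau (h).
#' @param n_doses Number of administrations.
#' @param start Time of the first dose (h), default 0.
#' @return A data frame with columns `time` and `amount`.
#' @export
dose_schedule <- function(amount, interval, n_doses, start = 0) {
  stopifnot(n_doses >= 1, interval > 0, amount > 0, start >= 0)
  data.frame(time = start + (seq_len(n_doses) - 1) * interval,
             amount = amount)
}

validate_schedule <- function(schedule) {
  if (is.null(schedule) || NROW(schedule) == 0) {
    stop("dose schedule must contain at least one dose", call. = FALSE)
  }
  schedule <- as.data.frame(schedule)
  if (!all(c("time", "amount") %in% names(schedule))) {
    stop("dose schedule needs `time` and `amount` columns", call. = FALSE)
  }
  if (any(schedule$amount <= 0)) {
    stop("dose amounts must be positive", call. = FALSE)
  }
  if (any(schedule$time < 0) || is.unsorted(schedule$time)) {
    stop("dose times must be non-negative and non-decreasing", call. = FALSE)
  }
  schedule
}

#' Steady-state trough concentration for regular oral dosing
#'
#' Closed-form minimum concentration at the end of a dosing interval once
#' accumulation has converged:
#' \deqn{C_{min,ss} = 1000 \frac{D}{V} \frac{K_a}{K_a - k_e}
#'   \left[\frac{e^{-k_e\tau}}{1 - e^{-k_e\tau}} -
#'         \frac{e^{-K_a\tau}}{1 - e^{-K_a\tau}}\right].}
#' Equals the long-run limit of [conc_superposition()] evaluated just before
#' a dose.
#'
#' @param dose_per_interval Dose per administration (mg).
#' @param tau Dosing interval (h), positive.
#' @param params An [individual_params()] object; fields may be vectors, in
#'   which case one trough per parameter set is returned.
#' @return Steady-state trough concentration(s), ng/mL.
#' @examples
#' steady_state_trough(14, 12, individual_params(19.6, 197, 0.861))
#' @export
steady_state_trough <- function(dose_per_interval, tau, params) {
  if (!inherits(params, "individual_params")) {
    stop("`params` must be an `individual_params` object", call. = FALSE)
  }
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(dose_per_interval)) || any(dose_per_interval <= 0)) {
    stop("`dose_per_interval` must be finite and positive", call. = FALSE)
  }
  .ss_trough(dose_per_interval, tau, params$cl, params$v, params$ka)
}

.ss_trough <- function(dose, tau, cl, v, ka) {
  ke <- cl / v
  accum <- function(k) exp(-k * tau) / (1 - exp(-k * tau))
  degenerate <- abs(ka - ke) < .KA_KE_REL_TOL * ka
  out <- 1000 * (dose / v) * ka / (ka - ke) * (accum(ke) - accum(ka))
  if (any(degenerate)) {
    # limit ka -> ke of the bracket / (ka - ke): tau e^{ke tau}/(e^{ke tau}-1)^2
    lim <- 1000 * (dose / v) * ke * tau * exp(ke * tau) / (expm1(ke * tau))^2 +
      0 * out
    deg <- rep_len(degenerate, length(out))
    out[deg] <- lim[deg]
  }
  out
}
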