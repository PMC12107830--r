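# Monte Carlo probability of target attainment (PTA) and initial-dose
# recommendation against the 20-80 ng/mL olanzapine trough window.

#' Therapeutic trough window (ng/mL)
#'
#' Inclusive steady-state trough target range for olanzapine.
#' @export
OLZ_WINDOW <- c(20, 80)

#' Dosing regimen
#'
#' @param dose_rate Weight-normalised daily dose (mg/kg/day), in (0, 2].
#' @param frequency `"qd"` (once daily) or `"bid"` (daily dose split evenly
#'   q12h).
#' @param par Paroxetine co-medication flag, 0 or 1.
#' @return A `regimen` object.
#' @export
regimen <- function(dose_rate, frequency = c("bid", "qd"), par = 0) {
  frequency <- match.arg(frequency)
  stopifnot(is.numeric(dose_rate), dose_rate > 0, dose_rate <= 2,
            par %in% c(0, 1))
  structure(list(dose_rate = dose_rate, frequency = frequency, par = par),
            class = "regimen")
}

#' Simulate probability of target attainment for one regimen cell
#'
#' Draws `n_virtual` clearance random effects, computes each virtual
#' patient's steady-state trough under the regimen (dose =
#' `dose_rate * weight` per day, tau = 24 h for qd or 12 h for bid with the
#' daily dose split evenly), and reports the fraction of troughs inside the
#' therapeutic window. By default the window is applied to true
#' (residual-error-free) troughs; `include_residual = TRUE` adds one
#' combined residual draw per patient instead.
#'
#' @param weight Body weight (kg).
#' @param reg A [regimen()].
#' @param pop A [pop_params()] object (defaults to the published model).
#' @param n_virtual Virtual patients (default 1000, the published setting).
#' @param seed Integer seed.
#' @param window Trough window, default [OLZ_WINDOW] (inclusive).
#' @param include_residual Apply the residual-error model to the troughs
#'   before the window check (default `FALSE`).
#' @return A `pta_entry`: list with `weight`, `regimen`, `n_virtual`,
#'   `pta` (fraction in the window), and `trough_summary` (percentiles of
#'   the simulated troughs).
#' @export
simulate_pta <- function(weight, reg, pop = pop_params(), n_virtual = 1000L,
                         seed = 1L, window = OLZ_WINDOW,
                         include_residual = FALSE) {
  stopifnot(inherits(reg, "regimen"), inherits(pop, "pop_params"),
            weight > 0, n_virtual >= 1)
  set.seed(seed)
  om <- omega_sd(pop)
  eta <- if (om > 0) stats::rnorm(n_virtual, 0, om) else rep(0, n_virtual)
  cov <- subject_covariates(weight = weight, par = reg$par)
  typ <- typical_params(cov, pop)
  ind <- individualize(
    individual_params(rep(typ$cl, n_virtual), rep(typ$v, n_virtual), typ$ka),
    eta)
  tau <- if (reg$frequency == "bid") 12 else 24
  dose <- reg$dose_rate * weight * tau / 24
  troughs <- steady_state_trough(dose, tau, ind)
  if (include_residual) {
    sv <- sigma_var(pop)
    troughs <- apply_residual(troughs,
                              stats::rnorm(n_virtual, 0, sqrt(sv[["prop"]])),
                              stats::rnorm(n_virtual, 0, sqrt(sv[["add"]])))
    troughs <- pmax(troughs, 0)
  }
  structure(list(weight = weight, regimen = reg, n_virtual = n_virtual,
                 pta = mean(troughs >= window[1] & troughs <= window[2]),
                 trough_summary = stats::quantile(
                   troughs, probs = c(0.025, 0.05, 0.25, 0.5, 0.75, 0.95, 0.975))),
            class = "pta_entry")
}

#' Probability-of-target-attainment grid
#'
#' One [simulate_pta()] cell per combination of weight, dose rate,
#' frequency and paroxetine status. The published design is 7 weights
#' (40-100 kg by 10) x 10 dose rates (0.1-1.0 mg/kg/day) x {qd, bid} x
#' {PAR 0, 1} with 1000 virtual patients per cell. Each cell gets its own
#' seed derived from the master seed and the cell's coordinates, so a
#' cell's PTA is invariant to grid order and to which other cells are
#' requested.
#'
#' @param weights Weights in kg (default `seq(40, 100, 10)`).
#' @param dose_rates mg/kg/day (default `seq(0.1, 1.0, 0.1)`).
#' @param frequencies Subset of `c("qd", "bid")`.
#' @param par_values Subset of `c(0, 1)`.
#' @param pop,n_virtual,window,include_residual Passed to [simulate_pta()].
#' @param seed Master seed.
#' @return A data frame (class `pta_grid`) with one row per cell: `weight`,
#'   `dose_rate`, `frequency`, `par`, `n_virtual`, `pta`, and trough
#'   percentile columns `p2.5` ... `p97.5`.
#' @export
pta_grid <- function(weights = seq(40, 100, 10),
                     dose_rates = seq(0.1, 1.0, 0.1),
                     frequencies = c("qd", "bid"), par_values = c(0, 1),
                     pop = pop_params(), n_virtual = 1000L, seed = 1L,
                     window = OLZ_WINDOW, include_residual = FALSE) {
  stopifnot(length(weights) > 0, length(dose_rates) > 0,
            all(frequencies %in% c("qd", "bid")), all(par_values %in% 0:1))
  cells <- expand.grid(weight = weights, dose_rate = dose_rates,
                       frequency = frequencies, par = par_values,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    entry <- simulate_pta(cell$weight,
                          regimen(cell$dose_rate, cell$frequency, cell$par),
                          pop = pop, n_virtual = n_virtual,
                          seed = cell_seed(seed, cell), window = window,
                          include_residual = include_residual)
    q <- entry$trough_summary
    rows[[i]] <- data.frame(weight = cell$weight, dose_rate = cell$dose_rate,
                            frequency = cell$frequency, par = cell$par,
                            n_virtual = n_virtual, pta = entry$pta,
                            p2.5 = q[[1]], p5 = q[[2]], p25 = q[[3]],
                            p50 = q[[4]], p75 = q[[5]], p95 = q[[6]],
                            p97.5 = q[[7]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pta_grid", class(out))
  out
}

# Deterministic per-cell seed from the master seed and cell coordinates,
# independent of grid enumeration order. Kept below 2^31.
cell_seed <- function(seed, cell) {
  key <- c(round(cell$weight * 10), round(cell$dose_rate * 100),
           ifelse(cell$frequency == "bid", 1, 2), cell$par + 1)
  h <- as.double(seed %% 2147483647)
  for (k in key) h <- (h * 31 + k) %% 2147480017
  as.integer(h)
}

#' Initial-dose recommendation from a PTA grid
#'
#' For one (frequency, paroxetine) slice: at each simulated weight the
#' recommended dose rate maximises PTA (ties go to the lower dose);
#' contiguous weights sharing a winner are merged into bands. Where
#' adjacent grid weights disagree, the band boundary is refined by
#' simulating intermediate weights at 1-kg steps and placing the cut at the
#' PTA crossover — this is how non-grid boundaries such as 56 kg arise from
#' a 10-kg grid.
#'
#' @param grid A [pta_grid()] covering all weights for the requested slice.
#' @param frequency `"qd"` or `"bid"`.
#' @param par 0 or 1.
#' @param pop,n_virtual,window,include_residual,seed Settings for boundary
#'   refinement simulations (should match how `grid` was built).
#' @return A `dose_recommendation`: data frame of bands with `weight_lo`,
#'   `weight_hi`, `dose_rate`, `pta_min`, `pta_max`.
#' @export
recommend_dose <- function(grid, frequency, par, pop = pop_params(),
                           n_virtual = 1000L, window = OLZ_WINDOW,
                           include_residual = FALSE, seed = 1L) {
  stopifnot(inherits(grid, "pta_grid") || is.data.frame(grid))
  slice <- grid[grid$frequency == frequency & grid$par == par, ]
  if (nrow(slice) == 0) stop("grid has no cells for this slice", call. = FALSE)
  weights <- sort(unique(slice$weight))
  dose_rates <- sort(unique(slice$dose_rate))
  complete <- nrow(slice) == length(weights) * length(dose_rates)
  if (!complete) {
    have <- with(slice, paste(weight, dose_rate))
    want <- with(expand.grid(w = weights, d = dose_rates), paste(w, d))
    stop(sprintf("incomplete slice; missing cells: %s",
                 paste(setdiff(want, have), collapse = ", ")), call. = FALSE)
  }
  winner <- vapply(weights, function(w) {
    sl <- slice[slice$weight == w, ]
    sl <- sl[order(sl$dose_rate), ]
    sl$dose_rate[which.max(sl$pta)]  # which.max: first max -> lower dose
  }, numeric(1))
  pta_at <- function(w, d) {
    cell <- data.frame(weight = w, dose_rate = d, frequency = frequency,
                       par = par)
    simulate_pta(w, regimen(d, frequency, par), pop = pop,
                 n_virtual = n_virtual, seed = cell_seed(seed, cell),
                 window = window, include_residual = include_residual)$pta
  }
  # band boundaries: refine between adjacent grid weights with different
  # winners at 1-kg resolution
  cuts <- numeric(0)
  for (i in seq_len(length(weights) - 1)) {
    if (winner[i] == winner[i + 1]) next
    w_seq <- seq(weights[i] + 1, weights[i + 1] - 1)
    cross <- weights[i + 1]
    for (w in w_seq) {
      if (pta_at(w, winner[i + 1]) > pta_at(w, winner[i])) {
        cross <- w
        break
      }
    }
    cuts <- c(cuts, cross)
  }
  lo <- c(min(weights), cuts)
  hi <- c(cuts, max(weights))
  band_dose <- winner[c(1, findInterval(cuts, weights) + 1)]
  # collapse any consecutive bands that ended up with the same dose
  bands <- data.frame(weight_lo = lo, weight_hi = hi, dose_rate = band_dose)
  keep <- c(TRUE, bands$dose_rate[-1] != bands$dose_rate[-nrow(bands)])
  merged <- bands[keep, , drop = FALSE]
  merged$weight_hi <- c(merged$weight_lo[-1], max(weights))
  # achieved PTA range per band over its grid weights
  merged$pta_min <- NA_real_
  merged$pta_max <- NA_real_
  for (b in seq_len(nrow(merged))) {
    in_band <- weights >= merged$weight_lo[b] & weights <= merged$weight_hi[b]
    # half-open bands except the last
    if (b < nrow(merged)) in_band <- in_band & weights < merged$weight_hi[b]
    p <- vapply(weights[in_band], function(w) {
      slice$pta[slice$weight == w & slice$dose_rate == merged$dose_rate[b]]
    }, numeric(1))
    merged$pta_min[b] <- min(p)
    merged$pta_max[b] <- max(p)
  }
  rownames(merged) <- NULL
  attr(merged, "frequency") <- frequency
  attr(merged, "par") <- par
  class(merged) <- c("dose_recommendation", class(merged))
  merged
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("Initial-dose recommendation (%s, %s paroxetine)\n",
              attr(x, "frequency"),
              if (attr(x, "par") == 1) "with" else "without"))
  for (b in seq_len(nrow(x))) {
    cat(sprintf("  [%g-%g%s kg: %.1f mg/kg/day (PTA %.1f-%.1f%%)\n",
                x$weight_lo[b], x$weight_hi[b],
                if (b < nrow(x)) ")" else "]",
                x$dose_rate[b], 100 * x$pta_min[b], 100 * x$pta_max[b]))
  }
  invisible(x)
}
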