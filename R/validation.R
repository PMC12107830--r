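# Model validation: goodness-of-fit residual tables, nonparametric
# bootstrap of the fit, and the visual predictive check.

#' Goodness-of-fit table
#'
#' One row per observation with the population prediction (PRED, at
#' eta = 0), individual prediction (IPRED, at the subject's empirical-Bayes
#' eta), individually weighted residual
#' iWRES = (DV - IPRED) / sqrt(Var(IPRED)), its absolute value, and the
#' population weighted residual WRES under the first-order approximation:
#' the subject's marginal mean and covariance are obtained by linearising
#' the eta-dependence at eta = 0 and WRES is the whitened residual vector.
#'
#' @param fit A `fit_result` (from [pk_fit()] or [as_fit()]).
#' @param dataset The dataset the fit was computed on.
#' @return A data frame with columns `id`, `time`, `dv`, `pred`, `ipred`,
#'   `wres`, `iwres`, `abs_iwres`, in dataset order.
#' @export
gof_table <- function(fit, dataset) {
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  pop <- fit$estimates
  om <- omega_sd(pop)
  sv <- sigma_var(pop)
  out <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    id <- as.character(s$id)
    eta_i <- fit$ebe[[id]]
    if (is.null(eta_i) || is.na(eta_i)) {
      stop(sprintf("no empirical-Bayes estimate for subject %s", id),
           call. = FALSE)
    }
    typ <- typical_params(s$covariates, pop)
    pred <- conc_superposition(s$doses, s$obs$time, typ)
    ipred <- conc_superposition(s$doses, s$obs$time, individualize(typ, eta_i))
    iwres <- (s$obs$dv - ipred) / sqrt(residual_variance(ipred, pop))
    # FO linearisation at eta = 0: dpred/deta by central difference
    h <- 1e-4
    gplus <- conc_superposition(s$doses, s$obs$time, individualize(typ, h))
    gminus <- conc_superposition(s$doses, s$obs$time, individualize(typ, -h))
    G <- (gplus - gminus) / (2 * h)
    V <- om^2 * tcrossprod(G) + diag(residual_variance(pred, pop),
                                     nrow = length(pred))
    L <- chol(V)
    wres <- backsolve(L, s$obs$dv - pred, transpose = TRUE)
    out[[i]] <- data.frame(id = id, time = s$obs$time, dv = s$obs$dv,
                           pred = pred, ipred = ipred, wres = as.vector(wres),
                           iwres = iwres, abs_iwres = abs(iwres))
  }
  do.call(rbind, out)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original subject count,
#' refits each replicate (starting from the original estimates, for speed
#' and stability), and summarises each free parameter by its bootstrap
#' median, 2.5th/97.5th percentile interval, and relative bias
#' \eqn{(median - estimate)/estimate \times 100\%}. Failed replicate fits
#' are dropped and counted; more than 20% failures is an error (an
#' unstable-model signal).
#'
#' @param dataset List of `subject_record`s.
#' @param fit The original `fit_result` (its estimates seed every
#'   replicate).
#' @param n_resamples Number of bootstrap replicates (production default
#'   1000; tests use far fewer).
#' @param seed Integer seed.
#' @param fixed,n_nodes Passed to [pk_fit()].
#' @param fit_fun Function `(dataset, init)` returning a `fit_result`;
#'   defaults to a [pk_fit()] wrapper. Injectable for testing.
#' @return A `bootstrap_summary`: data frame with `parameter`, `estimate`,
#'   `median`, `ci_lower`, `ci_upper`, `bias_pct`, plus attributes
#'   `n_resamples`, `n_failed`.
#' @export
bootstrap_model <- function(dataset, fit, n_resamples = 1000L, seed = 1L,
                            fixed = "ka", n_nodes = 41L, fit_fun = NULL) {
  stopifnot(n_resamples >= 2)
  params <- fit$free_params
  if (length(params) == 0) stop("fit has no free parameters", call. = FALSE)
  if (is.null(fit_fun)) {
    fit_fun <- function(ds, init) {
      pk_fit(ds, init = init, fixed = fixed, n_nodes = n_nodes,
             n_restarts = 0L, compute_se = FALSE)
    }
  }
  set.seed(seed)
  n <- length(dataset)
  draws <- matrix(NA_real_, n_resamples, length(params),
                  dimnames = list(NULL, params))
  n_failed <- 0L
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_data <- dataset[idx]
    for (k in seq_along(rep_data)) rep_data[[k]]$id <- k  # unique ids
    fb <- tryCatch(fit_fun(rep_data, fit$estimates), error = function(e) NULL)
    if (is.null(fb) || !isTRUE(fb$converged) || !is.finite(fb$ofv)) {
      n_failed <- n_failed + 1L
      next
    }
    draws[b, ] <- vapply(params, function(nm) get_param(fb$estimates, nm),
                         numeric(1))
  }
  if (n_failed > 0.2 * n_resamples) {
    stop(sprintf("bootstrap unstable: %d of %d replicate fits failed",
                 n_failed, n_resamples), call. = FALSE)
  }
  est <- vapply(params, function(nm) get_param(fit$estimates, nm), numeric(1))
  med <- apply(draws, 2, stats::median, na.rm = TRUE)
  lo <- apply(draws, 2, stats::quantile, probs = 0.025, na.rm = TRUE,
              names = FALSE)
  hi <- apply(draws, 2, stats::quantile, probs = 0.975, na.rm = TRUE,
              names = FALSE)
  out <- data.frame(parameter = params, estimate = est, median = med,
                    ci_lower = lo, ci_upper = hi,
                    bias_pct = bootstrap_bias(est, med),
                    row.names = NULL)
  attr(out, "n_resamples") <- n_resamples
  attr(out, "n_failed") <- n_failed
  class(out) <- c("bootstrap_summary", class(out))
  out
}

#' Bootstrap relative bias
#'
#' \eqn{(median - estimate) / estimate \times 100}, in percent.
#' @param estimate Original point estimate(s).
#' @param median Bootstrap median(s).
#' @return Bias in percent.
#' @export
bootstrap_bias <- function(estimate, median) {
  (median - estimate) / estimate * 100
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the fitted model with the
#' original design (same subjects, doses, observation times), then compares
#' observed 5th/50th/95th percentiles per time bin with the Monte-Carlo
#' distribution of the same percentiles across replicates. Bins are
#' quantiles of time after the most recent dose (TDM data cluster at
#' troughs, so absolute time carries little signal).
#'
#' @param fit A converged `fit_result`.
#' @param dataset The dataset the fit was computed on.
#' @param n_sim Number of simulated replicates (>= 100; default 500).
#' @param seed Integer seed.
#' @param n_bins Number of time-after-dose bins (default 4).
#' @return A `vpc_result`: data frame with one row per bin and percentile
#'   (5, 50, 95): observed value, simulated median and 2.5/97.5% band, bin
#'   edges, `n_obs` (bins with fewer than 5 observations are flagged via
#'   `sparse_bin`).
#' @export
vpc <- function(fit, dataset, n_sim = 500L, seed = 1L, n_bins = 4L) {
  stopifnot(inherits(fit, "fit_result"), n_sim >= 100)
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  pop <- fit$estimates
  tad <- unlist(lapply(dataset, function(s) {
    vapply(s$obs$time, function(t) t - max(s$doses$time[s$doses$time < t]),
           numeric(1))
  }))
  dv <- unlist(lapply(dataset, function(s) s$obs$dv))
  edges <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(edges) < 2) edges <- range(tad) + c(-1e-9, 1e-9)
  bin <- cut(tad, breaks = edges, include.lowest = TRUE)
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(levels(bin), function(b) {
    stats::quantile(dv[bin == b], probs = probs, names = FALSE)
  }, numeric(3)))
  sim_pct <- array(NA_real_, c(n_sim, nlevels(bin), 3))
  for (r in seq_len(n_sim)) {
    simd <- simulate_dataset(dataset, pop, seed = seed + r - 1L)
    dv_r <- unlist(lapply(simd, function(s) s$obs$dv))
    for (b in seq_len(nlevels(bin))) {
      sel <- bin == levels(bin)[b]
      sim_pct[r, b, ] <- stats::quantile(dv_r[sel], probs = probs,
                                         names = FALSE)
    }
  }
  rows <- list()
  for (b in seq_len(nlevels(bin))) {
    for (k in seq_len(3)) {
      band <- stats::quantile(sim_pct[, b, k], probs = c(0.025, 0.5, 0.975),
                              names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        bin = levels(bin)[b], n_obs = sum(bin == levels(bin)[b]),
        percentile = 100 * probs[k], observed = obs_pct[b, k],
        sim_lower = band[1], sim_median = band[2], sim_upper = band[3])
    }
  }
  out <- do.call(rbind, rows)
  out$sparse_bin <- out$n_obs < 5
  if (any(out$sparse_bin)) {
    warning("some VPC bins contain fewer than 5 observations")
  }
  attr(out, "n_sim") <- n_sim
  class(out) <- c("vpc_result", class(out))
  out
}
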