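pop_truth <- pop_params()

test_that("GOF table on noise-free data collapses to the predictions", {
  # IIV only, no residual noise in the data; diagnostics computed under a
  # small additive variance so weighting is defined. EBEs recover the etas
  # and DV == IPRED up to that (negligible) shrinkage.
  pop_sim <- pop_params(omega_cl = 0.4, sigma_prop = 0, sigma_add = 0)
  pop_diag <- pop_params(omega_cl = 0.4, sigma_prop = 0, sigma_add = 0.01)
  ds <- simulate_dataset(draw_cohort(cohort_design(n_subjects = 12), seed = 91),
                         pop_sim, seed = 92)
  gof <- gof_table(as_fit(ds, pop_diag), ds)
  expect_equal(nrow(gof), sum(vapply(ds, function(s) nrow(s$obs), integer(1))))
  expect_lt(max(abs(gof$dv - gof$ipred)), 0.01)
  expect_lt(max(abs(gof$iwres)), 0.05)
  # fully deterministic model: DV = IPRED = PRED exactly
  pop0_sim <- pop_params(omega_cl = 0, sigma_prop = 0, sigma_add = 0)
  pop0_diag <- pop_params(omega_cl = 0, sigma_prop = 0, sigma_add = 0.01)
  ds0 <- simulate_dataset(draw_cohort(cohort_design(n_subjects = 6), seed = 93),
                          pop0_sim, seed = 94)
  gof0 <- gof_table(as_fit(ds0, pop0_diag), ds0)
  expect_equal(gof0$dv, gof0$pred, tolerance = 1e-12)
  expect_equal(gof0$dv, gof0$ipred, tolerance = 1e-12)
  expect_identical(gof0$iwres, rep(0, nrow(gof0)))
  expect_equal(gof0$abs_iwres, abs(gof0$iwres))
})

test_that("residuals are standardised under the generating model", {
  ds <- simulate_dataset(draw_cohort(cohort_design(n_subjects = 400), seed = 95),
                         pop_truth, seed = 96)
  gof <- gof_table(as_fit(ds, pop_truth), ds)
  expect_equal(gof$abs_iwres, abs(gof$iwres))
  # shrinkage towards the EBE pulls the iWRES spread slightly below 1 and
  # leaves a small negative mean; FO-WRES over-disperses because the
  # linearisation understates the marginal variance at 39% proportional
  # error -- bounds are correspondingly loose
  expect_lt(abs(mean(gof$iwres)), 0.15)
  expect_gt(sd(gof$iwres), 0.7)
  expect_lt(sd(gof$iwres), 1.1)
  expect_lt(abs(mean(gof$wres)), 0.25)
  expect_gt(sd(gof$wres), 0.6)
  expect_lt(sd(gof$wres), 1.7)
})

test_that("bootstrap summarises resamples correctly (stub fitter oracle)", {
  ds <- simulate_dataset(draw_cohort(cohort_design(n_subjects = 30), seed = 97),
                         pop_truth, seed = 98)
  # stub: "estimate" is the mean DV of the resampled dataset
  stub_fit <- function(d, init) {
    m <- mean(unlist(lapply(d, function(s) s$obs$dv)))
    structure(list(estimates = set_tv(init, m), converged = TRUE, ofv = 0,
                   free_params = "tv_cl"),
              class = "fit_result")
  }
  set_tv <- function(pop, v) { pop$tv_cl <- v; pop }
  orig <- structure(list(estimates = pop_truth, converged = TRUE, ofv = 0,
                         free_params = "tv_cl"),
                    class = "fit_result")
  bs <- bootstrap_model(ds, orig, n_resamples = 2, seed = 5,
                        fit_fun = stub_fit)
  # oracle: replay the resampling with the same seed
  set.seed(5)
  draws <- vapply(1:2, function(b) {
    idx <- sample.int(30, 30, replace = TRUE)
    mean(unlist(lapply(ds[idx], function(s) s$obs$dv)))
  }, numeric(1))
  expect_equal(bs$median, median(draws))
  expect_equal(bs$ci_lower, unname(quantile(draws, 0.025)))
  expect_equal(bs$ci_upper, unname(quantile(draws, 0.975)))
  expect_equal(bs$bias_pct, (median(draws) - 19.6) / 19.6 * 100)
  expect_true(bs$ci_lower <= bs$median && bs$median <= bs$ci_upper)
  # determinism
  bs2 <- bootstrap_model(ds, orig, n_resamples = 2, seed = 5,
                         fit_fun = stub_fit)
  expect_identical(as.data.frame(bs), as.data.frame(bs2))
  # CI from a smaller cohort is (weakly) wider, same protocol
  bs_small <- bootstrap_model(ds[1:8], orig, n_resamples = 100, seed = 5,
                              fit_fun = stub_fit)
  bs_large <- bootstrap_model(ds, orig, n_resamples = 100, seed = 5,
                              fit_fun = stub_fit)
  expect_gte(bs_small$ci_upper - bs_small$ci_lower,
             bs_large$ci_upper - bs_large$ci_lower)
})

test_that("bias formula behaves as an exact identity", {
  expect_equal(bootstrap_bias(19.6, 19.4), (19.4 - 19.6) / 19.6 * 100)
  expect_equal(bootstrap_bias(5, 5), 0)
  expect_equal(bootstrap_bias(2, 3), 50)
  expect_equal(bootstrap_bias(3, 2), -100 / 3)
})

test_that("bootstrap with real refits runs and respects the failure guard", {
  ds <- simulate_dataset(draw_cohort(cohort_design(n_subjects = 15), seed = 99),
                         pop_truth, seed = 100)
  fit <- structure(list(estimates = pop_truth, converged = TRUE, ofv = 0,
                        free_params = c("tv_cl", "tv_v")),
                   class = "fit_result")
  bs <- bootstrap_model(ds, fit, n_resamples = 3, seed = 7,
                        fixed = c("ka", "omega_cl", "sigma_prop", "sigma_add",
                                  "theta_par_cl"))
  expect_equal(attr(bs, "n_resamples"), 3)
  expect_lte(attr(bs, "n_failed"), 0)
  expect_true(all(bs$ci_lower <= bs$median & bs$median <= bs$ci_upper))
  # a fitter that always fails trips the stability guard
  bad_fit <- function(d, init) stop("boom")
  expect_error(bootstrap_model(ds, fit, n_resamples = 4, seed = 7,
                               fit_fun = bad_fit), "unstable")
})

test_that("VPC is self-consistent, deterministic, and collapses without noise", {
  ds <- simulate_dataset(draw_cohort(cohort_design(n_subjects = 100), seed = 103),
                         pop_truth, seed = 104)
  v <- vpc(as_fit(ds, pop_truth), ds, n_sim = 150, seed = 9)
  # observed percentiles fall inside the simulated bands most of the time
  inside <- v$observed >= v$sim_lower & v$observed <= v$sim_upper
  expect_gte(mean(inside), 0.75)
  expect_true(all(v$sim_lower <= v$sim_median & v$sim_median <= v$sim_upper))
  v2 <- vpc(as_fit(ds, pop_truth), ds, n_sim = 150, seed = 9)
  expect_identical(as.data.frame(v), as.data.frame(v2))
  # deterministic model: bands collapse onto the prediction line
  pop0 <- pop_params(omega_cl = 0, sigma_prop = 0, sigma_add = 1e-12)
  ds0 <- simulate_dataset(draw_cohort(cohort_design(n_subjects = 40), seed = 105),
                          pop0, seed = 106)
  v0 <- vpc(as_fit(ds0, pop0), ds0, n_sim = 100, seed = 10)
  expect_lt(max(v0$sim_upper - v0$sim_lower), 1e-3)
  expect_lt(max(abs(v0$observed - v0$sim_median)), 1e-3)
})
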