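---
title: "Methods: olanzapine population pharmacokinetics and initial-dose optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: olanzapine population pharmacokinetics and initial-dose optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olanzpk)
```

## The model

`olanzpk` implements a population-pharmacokinetic (popPK) analysis of
olanzapine trough concentrations measured by routine therapeutic drug
monitoring (TDM) in adults treated for major depressive disorder, and the
Monte Carlo dose-optimization layer built on top of it.

The structural model is a one-compartment disposition with first-order
absorption, parameterised by apparent oral clearance CL/F (L/h), apparent
volume V/F (L) and a fixed absorption constant Ka = 0.861 h⁻¹. Only the
ratios CL/F and V/F are identifiable from oral data; no separate
bioavailability is carried. After a dose D at time 0,

$$C(t) = \frac{1000\,D}{V}\,\frac{K_a}{K_a - k_e}\left(e^{-k_e t} - e^{-K_a t}\right),
\qquad k_e = CL/V,$$

in ng/mL (the factor 1000 converts mg/L). Multiple dosing uses linear
superposition, and steady-state troughs use the closed geometric-series
form (`steady_state_trough()`). The degenerate case $K_a \to k_e$ switches
to the analytic limit when $|K_a - k_e| < 10^{-8} K_a$, avoiding
catastrophic cancellation.

Between-subject structure:

* allometric weight scaling with fixed exponents,
  $CL \propto (WT/70)^{0.75}$, $V \propto (WT/70)^{1}$;
* a linear categorical drug–drug-interaction effect of paroxetine on
  clearance, $CL \times (1 + \theta_{PAR}\,PAR)$ with
  $\theta_{PAR} = -0.289$, i.e. a 0.711 : 1 clearance ratio with : without
  paroxetine at any weight (paroxetine inhibits the CYP enzyme that
  metabolises olanzapine);
* lognormal inter-individual variability on clearance only,
  $CL_i = CL_{typ} e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$;
* a combined residual, $B = C(1 + \epsilon_1) + \epsilon_2$, giving
  $\mathrm{Var}(B \mid C) = C^2\sigma_1^2 + \sigma_2^2$.

The shipped defaults are the published final estimates: typical CL/F 19.6
L/h and V/F 197 L at 70 kg, $\theta_{PAR} = -0.289$, $\omega_{CL} = 0.434$,
$\sigma_1 = 0.153$, $\sigma_2 = 1.005$ ng/mL.

## The variability-scale calibration

The source table reports single numbers for $\omega$ and $\sigma$ without
stating whether they are standard deviations or variances (both conventions
exist in NONMEM reporting). The package resolves this empirically and ships
the calibrated reading as the default, with both choices exposed
(`omega_scale`, `sigma_scale` in `pop_params()`):

* **$\omega$ is an SD (0.434, i.e. ~43% CV).** Only this reading
  reproduces the published probability-of-target-attainment (PTA) tables:
  with $\omega = 0.434$ as SD the twice-daily 0.4 mg/kg/day no-paroxetine
  regimen attains ~67–70% PTA against the printed 68.5–72.6%, and the
  once-daily maximum stays below the printed 55% ceiling; the variance
  reading puts every regimen near 50% and the bands off by more than
  15 points.
* **$\sigma_1, \sigma_2$ are SDs (15.3% proportional, 1.005 ng/mL
  additive).** The PTA oracle cannot discriminate these (PTA uses true
  troughs), but three independent arguments agree: the table prints
  $\omega$ and $\sigma$ in the same column, and $\omega$ is demonstrably an
  SD; a synthetic 72-subject refit reproduces the published relative
  standard errors far better under the SD reading; and a 39% proportional
  assay/model error (the variance reading) is implausible for LC-based TDM.

PTA simulations apply the therapeutic window to *true* troughs, without
residual error (`include_residual = FALSE` by default): adding measurement
noise would smear ~4–8 points off every band and cannot reproduce the
printed tables.

## Estimation

The model has exactly one random effect, so the marginal likelihood of a
subject is a 1-D integral over $\eta$. Each evaluation finds the subject's
conditional mode by a vectorised damped Newton iteration (secant-in-log
start, per-subject backtracking, per-subject `optimize()` fallback), then
integrates with one of two rules:

* **Adaptive Gauss–Hermite, 41 nodes (default).** Centred and scaled at
  the mode. This is far more accurate than the first-order conditional
  approximations it stands in for, but it has an irreducible error floor of
  about $10^{-5}$ absolute log-likelihood for sparse subjects: under the
  combined residual model the conditional density has a *flat* tail (at
  extreme $\eta$ the likelihood tends to a constant, so the joint density
  keeps a prior-scale shoulder), and Gauss–Hermite with mode-scaled nodes
  cannot integrate a function that grows like $e^{x^2}$ against its weight
  — more nodes plateau rather than converge. An error of $10^{-5}$ per
  subject is immaterial for estimation: it perturbs a 300-subject OFV by
  ~0.01 against decision thresholds of 3.84/6.63.
* **Dense spliced trapezoid (`method = "dense"`).** A fine uniform grid
  across the conditional peak (mode ± 10 s, 161 points) joined at exactly
  evaluated boundaries to coarse prior-scale grids covering ±7ω. On uniform
  grids the Euler–Maclaurin error sits entirely in boundary derivatives,
  which vanish where the integrand is flat; the rule agrees with
  brute-force Simpson integration to better than $10^{-7}$ and is used
  wherever that level of accuracy is asserted. About 3× the cost of AGQ.

The OFV is $-2\sum_i \log L_i$. `pk_fit()` minimises it with `nlminb` on
transformed parameters (log scale for positivity-constrained parameters,
identity for covariate coefficients with a smooth admissibility penalty
keeping $1 + \theta\,cov > 0.01$), restarted from jittered initial values;
convergence requires relative OFV change $< 10^{-8}$ and parameter change
$< 10^{-6}$. The objective is a deterministic function of the parameters
(mode search always restarts from a fixed state) — without this, finite
difference gradients pick up mode-warm-start noise and the optimiser
reports false convergence. Standard errors come from the inverse Hessian of
OFV/2 at the optimum (delta method back to the natural scale); SE% is
100·SE/|estimate|. Empirical-Bayes $\eta$ estimates are the conditional
modes at the final parameters.

Stepwise covariate selection follows the classical OFV rules: forward
inclusion requires a drop > 3.84 (α ≈ 0.05, χ²₁), backward retention
requires that removal raises the OFV by > 6.63 (α ≈ 0.01). Ties prefer
fewer parameters, then lexical order, for determinism.

## The synthetic cohort

No patient data are published, so every downstream stage is exercised on
synthetic cohorts (`cohort_design()`, `draw_cohort()`,
`simulate_dataset()`) that emulate the study's published margins: 72
subjects, weights truncated-normal (mean 61.83, SD 11.82, bounded 40–92
kg), 25% on paroxetine, 1–3 trough-timed samples per subject at steady
state. Doses and sampling times are **not** published; the defaults are
deliberate design choices:

* total daily dose drawn per subject from {5, 10, 15, 20} mg/day (plausible
  maintenance dosing);
* each subject independently once-daily or twice-daily with equal
  probability (both regimens are routine for olanzapine, and the source
  analysis itself simulates both);
* observations at the end of a dosing interval minus a uniform 0–4 h
  jitter, emulating blood draws taken up to a few hours before the next
  dose.

The last two choices matter for a reason worth recording: if every sample
sits at *exactly* one time after dose under a single dosing interval, the
data constrain only the trough value and (CL/F, V/F, ω) collapse onto a
flip-flop-like likelihood ridge — refits then wander to, e.g., CL/F ≈ 3
L/h, V/F ≈ 8 L with a *better* likelihood than the truth. Real TDM
sampling is never that degenerate; the mixed-frequency, jittered default
restores identifiability (recovery across seeds: CL/F ≈ 18–21 L/h, V/F ≈
170–220 L, θ ≈ −0.2 to −0.37). Exact-trough single-frequency designs
remain available and are still correct for simulation-only use.

What a green test on synthetic data does establish: the estimation
machinery recovers the generating model from data of the published
sparsity, and the simulation/PTA layer reproduces the published dose
tables from the published parameters. What it cannot establish: anything
about the real cohort's unpublished doses, sampling times, or data quality
— notably, the published standard errors (7.1% on CL/F at n = 72) are
tighter than any emulation we can build from the published margins, so
synthetic-refit scatter is larger than the printed SEs suggest.

## Dose optimization

`pta_grid()` reproduces the published simulation design: 7 weight groups
(40–100 kg) × 10 dose rates (0.1–1.0 mg/kg/day) × {once daily, twice daily
split evenly} × {with, without paroxetine}, 1000 virtual patients per cell,
steady-state troughs from the closed form, target window 20–80 ng/mL
inclusive on both ends. Each cell derives its seed from the master seed and
its own coordinates, so results are invariant to grid order. Doses are
exact mg (rate × weight), not rounded to tablet strengths.

`recommend_dose()` picks, per weight, the dose maximising PTA (ties to the
lower dose), merges contiguous weights with the same winner into bands, and
refines band boundaries at 1-kg steps by locating the PTA crossover — this
is a reconstruction of how non-grid boundaries (e.g. 56 kg) can arise from
a 10-kg grid, not a published procedure.

With the calibrated defaults the reproduced PTA values sit consistently
about 1.5–2.5 percentage points *below* the printed band edges (e.g.
twice-daily 0.3 mg/kg/day with paroxetine: ~71.8–73.6% against printed
74.4–76.7%). The ordering, the once-daily < 55% ceiling, and the
recommended doses all reproduce; the small uniform deficit cannot be
attributed from the publication (candidate explanations — trough sampled
slightly before the interval end, or truncated η draws — are unstated
there, and we do not adopt unstated mechanisms to close a gap).

## Validation layer

* `gof_table()`: PRED (η = 0), IPRED (η = EBE), iWRES standardised by the
  residual SD at IPRED, and population WRES under the first-order
  approximation (marginal covariance from the η-gradient at 0). iWRES is
  slightly shrunk below unit SD by empirical-Bayes estimation; FO-WRES
  over-disperses somewhat at a 15% proportional error. Which weighted
  residual the original authors plotted is unstated; FO-WRES is the
  classical default.
* `bootstrap_model()`: plain nonparametric resampling of subjects to the
  original count, refit per replicate from the original estimates,
  percentile 95% CI and bias = (median − estimate)/estimate × 100%.
  Replicate failures are counted and > 20% is an error.
* `vpc()`: simulates replicates under the fitted model with the original
  design and compares observed 5/50/95th percentiles per
  time-after-last-dose bin (quantile bins, default 4 — TDM data cluster at
  troughs, so absolute time carries little signal) against the Monte-Carlo
  band of the same statistic.

## Known limitations

* One compartment, no absorption lag, no IIV on V/F or Ka, no correlated
  random effects — the published model's exact scope.
* V/F is weakly identified from trough-dominated data; its single-fit
  sampling scatter is ~10–15% even at 300 subjects, which is why the
  acceptance experiment reports the mean of three independent replicates.
* The ~2-point PTA deficit against the printed bands, as above.
* Below-limit-of-quantification handling is absent (none reported in the
  source data).
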