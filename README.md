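# olanzpk

Population pharmacokinetics of olanzapine in adults treated for major
depressive disorder, with paroxetine as a drug–drug-interaction covariate,
and Monte Carlo optimization of the initial dose against the 20–80 ng/mL
therapeutic trough window.

Olanzapine dosing in this population is usually adjusted retrospectively
from therapeutic drug monitoring (TDM), which cannot inform the *first*
dose. This package implements the complete quantitative pipeline that turns
sparse TDM troughs into an initial-dose recommendation:

1. **Structural PK** — one-compartment, first-order absorption
   (CL/F, V/F, Ka fixed at 0.861 h⁻¹), closed-form single-dose,
   superposition and steady-state trough solutions;
2. **Population model** — allometric weight scaling
   (CL/F ∝ (WT/70)^0.75, V/F ∝ WT/70), a linear paroxetine effect on
   clearance (θ_PAR = −0.289, i.e. clearance ratio 0.711:1 with:without
   paroxetine at equal weight), lognormal inter-individual variability on
   CL/F (ω = 0.434), combined proportional + additive residual error:

   CL/F = 19.6 × (WT/70)^0.75 × (1 − 0.289·PAR)  L/h
   V/F  = 197 × (WT/70)  L

3. **NLME estimation** — exact 1-D adaptive Gauss–Hermite marginal
   likelihood (one random effect), OFV-based stepwise covariate selection
   (in: ΔOFV > 3.84, out: ΔOFV > 6.63), standard errors, empirical-Bayes
   estimates;
4. **Validation** — goodness-of-fit residual tables (PRED/IPRED/WRES/iWRES),
   subject-resampling bootstrap with percentile CIs and bias, visual
   predictive check;
5. **Synthetic cohorts** — virtual TDM studies matching the published
   cohort margins (n = 72, weight 61.8 ± 11.8 kg in [40, 92], 25% on
   paroxetine, 1–3 steady-state troughs each), since the patient-level data
   are not public;
6. **Dose optimization** — probability of target attainment (PTA): 1000
   virtual patients per cell over 7 weights × 10 doses × {qd, bid} ×
   {±paroxetine}, steady-state troughs scored against 20–80 ng/mL, and
   banded mg/kg/day recommendations.

## Worked example

```r
library(olanzpk)

pop <- pop_params()          # the published final model
p70 <- typical_params(subject_covariates(weight = 70, par = 0), pop)
p70
#> Individual PK parameters: CL/F = 19.6 L/h, V/F = 197 L, Ka = 0.861 1/h (ke = 0.09949 1/h)

steady_state_trough(14, 12, p70)   # 14 mg q12h = 0.4 mg/kg/day bid at 70 kg
#> [1] 34.93325
```

A typical 70-kg patient on 0.4 mg/kg/day split twice daily has a
steady-state trough of ~35 ng/mL — mid-window. Across the variable
population:

```r
simulate_pta(70, regimen(0.4, "bid", par = 0), pop, n_virtual = 1000, seed = 1)$pta
#> [1] 0.675
```

67.5% of virtual 70-kg patients fall inside 20–80 ng/mL. Scanning the full
grid and recommending per weight band:

```r
grid <- pta_grid(frequencies = "bid", par_values = 0, pop = pop,
                 n_virtual = 1000, seed = 1)
recommend_dose(grid, "bid", 0, pop = pop, n_virtual = 1000, seed = 1)
#> Initial-dose recommendation (bid, without paroxetine)
#>   [40-41) kg: 0.5 mg/kg/day (PTA 66.7-66.7%)
#>   [41-100] kg: 0.4 mg/kg/day (PTA 66.2-72.8%)
```

0.5 mg/kg/day wins at the lowest weights and 0.4 mg/kg/day above — the
published pattern. The exact low-weight boundary is noisy at 1000 patients
per cell because the two doses differ by under 2 PTA points below ~56 kg.

Refitting a synthetic cohort of the published size recovers the model:

```r
ds <- simulate_dataset(draw_cohort(cohort_design(n_subjects = 72), seed = 1),
                       pop, seed = 2)
pk_fit(ds)
#> NLME fit: 72 subjects, 142 observations, OFV = 886.145 (converged)
#>     parameter    estimate          se  rse_pct
#>         tv_cl  21.7881720  2.92560220 13.42748
#>          tv_v 208.2888729 53.62030992 25.74324
#>      omega_cl   0.4462796  0.05309675 11.89764
#>    sigma_prop   0.1382281  0.01829939 13.23855
#>     sigma_add   1.0404644  0.19014327 18.27485
#>  theta_par_cl  -0.3524317  0.08095603 22.97070
```

End-to-end runs (simulate → fit → validate → PTA) are available as
`run_pipeline(config)` or from the shell:

```sh
Rscript -e 'olanzpk::pk_cli()' run-all --seed 1 --out out/
```

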