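Package: olanzpk
Title: Population Pharmacokinetics and Initial Dose Optimization of
    Olanzapine in Major Depressive Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects population-pharmacokinetic analysis of
    olanzapine trough concentrations from sparse therapeutic drug monitoring
    in adults with major depressive disorder. Implements the one-compartment
    oral model with allometric weight scaling and a paroxetine drug-drug
    interaction effect on clearance, maximum marginal-likelihood estimation
    by adaptive Gauss-Hermite quadrature, stepwise covariate selection on
    objective-function-value criteria, bootstrap/VPC/goodness-of-fit
    validation, synthetic cohort simulation, and Monte Carlo
    probability-of-target-attainment dose optimization against the
    20-80 ng/mL therapeutic window.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
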