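# curefrail

Mixture cure and mixture cure frailty survival models for cohorts with
long-term survivors, fitted by EM with a nonparametric (Breslow) baseline.

## What problem this solves

In long-follow-up cohorts — the motivating case is a registry of 2170
HIV-infected individuals followed for up to two decades — a sizeable
subpopulation never experiences the event of interest. The Kaplan–Meier
curve flattens well above zero and censoring is heavy (57.5% in the
reference cohort), and a conventional Cox model, which assumes everyone is
susceptible, misstates long-run risk. Mixture cure models split the
population survival into

    S_pop(t | X, Z) = pi(Z) * S_u(t | X) + 1 - pi(Z)

with a logistic *incidence* part `pi(Z)` (probability of being uncured,
i.e. susceptible) and a proportional-hazards *latency* part
`S_u(t | X) = exp(-H0(t) e^{beta'X})` for the uncured, so covariates can
act separately on long-term (cure) and short-term (hazard) survival. The
frailty variant multiplies the uncured hazard by a subject-level
`w ~ Gamma(1/psi, scale psi)` (mean 1, variance `psi`) to absorb
unmeasured heterogeneity; marginally the uncured survival becomes
`(1 + psi * H(t))^(-1/psi)`.

The package is aimed at biostatisticians analysing epidemiological
cohorts with a plausible cured fraction, and includes everything around
the models: cohort validation and multiple imputation, VIF collinearity
checks, Kaplan–Meier plateau detection, the Maller–Zhou test for a cure
fraction, `ln(-ln S)` proportional-hazards diagnostics, bootstrap
standard errors, Wald (OR/HR) tables, a concordance measure for cure
models (K-index) and a synthetic cohort generator with known ground
truth calibrated to the reference cohort's published summaries.

## Worked example

```r
library(curefrail)

# a synthetic cohort at the published study conditions, censoring
# calibrated to 57.5%
cfg <- calibrate_censoring(default_hiv_config(), target_rate = 0.575)
sim <- simulate_cohort(cfg, seed = 42)
ch  <- sim$cohort
ch
#> Cohort: 2170 subjects, 940 deaths (56.7% censored), 10 covariates

maller_zhou_test(ch)
#> Maller-Zhou cure-fraction test
#>   estimated cure fraction: 0.4713 (SE 0.0132)
#>   z = 35.406, one-sided p = 6.881e-275 -> cure fraction > 0 at level 0.05
#>   N_n = 7, alpha_n = 0.0032, sufficient follow-up: TRUE

fit <- fit_mixture_cure_frailty(ch)
fit$psi          # frailty variance estimate for this replicate
#> [1] 0.1304258

# which model fits better?
ph <- fit_mixture_cure_ph(ch)
compare_models(list(cure_ph = ph, cure_frailty = fit), ch)
#>         model   k_index    loglik n_parameters
#>       cure_ph 0.7467158 -7346.858           21
#>  cure_frailty 0.7467180 -7346.528           22
#> preferred by K-index: cure_frailty

# odds ratios (incidence) and hazard ratios (latency) with bootstrap CIs
fit_se <- fit_mixture_cure_frailty(ch, se = "bootstrap", B = 100, seed = 1)
wald_table(fit_se)

# per-subject probability of cure, 1 - logit^-1(theta'Z)
head(round(cure_probability(fit, ch$data[, fit$incidence_covariates]), 4))
#> [1] 0.0841 0.0841 0.1722 0.8498 0.1399 0.5891
```

The Maller–Zhou output says the Kaplan–Meier plateau (here at survival
0.47) is far too high to be a censoring artefact, i.e. the cohort
contains long-term survivors, which is the licence for a cure model. The
`wald_table()` rows are read like any logistic/Cox table: an incidence OR
above 1 means higher odds of being *uncured* (worse long-term prognosis),
a latency HR above 1 means faster death among the uncured.

`run_pipeline()` chains all of the above (imputation, VIF, diagnostics,
both fits, tables, K-index comparison) and can write every output as CSV
and JSON files plus a run log.

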