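---
title: "Mixture cure and mixture cure frailty models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture cure and mixture cure frailty models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curefrail)
```

## The problem

In long follow-up cohorts of people living with HIV, a substantial share of
subjects never experiences the event of interest (death from the disease):
they are *cured* or *non-susceptible* in the survival-analysis sense. Their
presence shows up as a Kaplan–Meier curve that flattens well above zero and
as heavy censoring. A conventional Cox model treats everyone as susceptible
and therefore overstates long-run mortality; mixture cure models instead
split the population into a cured fraction and an uncured (susceptible)
fraction and model the two layers separately, so that covariates can act
differently on *whether* a subject can die of the disease (long-term,
"incidence") and on *when* an uncured subject dies (short-term, "latency").

## Models

**Semiparametric PH mixture cure model.** The population survival function
is the two-component mixture

$$S_{pop}(t \mid X, Z) = \pi(Z)\, S_u(t \mid X) + 1 - \pi(Z),$$

where $\pi(Z) = \operatorname{logit}^{-1}(b^\top Z)$ is the probability of
being uncured (the *incidence* part) and
$S_u(t \mid X) = \exp\{-H_0(t)\, e^{\beta^\top X}\}$ is a proportional
hazards model for the uncured (the *latency* part) with an unspecified
baseline cumulative hazard $H_0$ carried as a step function with jumps at
observed event times (Breslow form).

**Mixture cure frailty model.** A latent indicator $v_i$ marks subject $i$
as uncured ($v_i = 1$, probability $\pi_i = \operatorname{logit}^{-1}
(\theta^\top Z_i)$). Conditional on being uncured, the hazard is
$w_i\, h_0(t)\, e^{\beta^\top X_i}$ with a subject-level frailty
$w_i \sim \Gamma(1/\Psi, \text{scale } \Psi)$ — mean 1, variance $\Psi$ —
absorbing unmeasured heterogeneity. Integrating the frailty out gives the
marginal uncured survival $(1 + \Psi H_i(t))^{-1/\Psi}$, with
$\exp(-H_i(t))$ as the $\Psi \to 0$ limit; continuity at that boundary is
verified numerically in the test suite.

## Estimation

Both models are fitted by EM on the complete-data likelihood
$L_{i,c} = (1-\pi_i)^{1-v_i} (\pi_i G_i)^{v_i}$, where for the frailty
model $G_i$ multiplies the gamma frailty density, the hazard contribution
$[w_i h_0(t_i) e^{\beta^\top X_i}]^{\delta_i}$ and the survival factor
$e^{-w_i H_i(t_i)}$.

* **E-step.** $E[v_i] = 1$ for deaths; for censored subjects
  $\pi_i S_u(t_i) / (1 - \pi_i + \pi_i S_u(t_i))$, with the
  frailty-marginal $S_u$ in the frailty model. Gamma conjugacy makes the
  frailty posterior available in closed form,
  $w_i \mid \text{uncured, data} \sim \Gamma(1/\Psi + \delta_i,\
  \text{scale } \Psi/(1+\Psi H_i))$, so the E-step needs only
  $E[w_i]$ and $E[\log w_i]$.
* **M-step.** The incidence coefficients come from a logistic regression
  with fractional responses $E[v_i]$; the latency coefficients from a Cox
  partial likelihood (Breslow ties) with case weights $E[v_i]$ and, in the
  frailty model, offset $\log E[w_i]$; the baseline from the weighted
  Breslow increment formula. These are exactly the maximisers of the
  expected complete-data log-likelihood profiled over the step baseline,
  so the observed-data log-likelihood is nondecreasing across iterations —
  an invariant asserted on every fit in the test suite.
* **$\Psi$ update.** The expected-complete-data update for a variance
  component contracts at the damped EM rate and crawls near its optimum
  (and near the $\Psi = 0$ boundary). The package instead updates $\Psi$
  by a bracketed one-dimensional maximisation of the *observed-data*
  log-likelihood on $[10^{-8}, 50]$ (log scale) given the other
  parameters. Each such step can only increase the observed likelihood,
  the overall scheme remains monotone coordinate ascent, and its fixed
  point coincides with the EM fixed point; the practical difference is
  convergence in tens rather than thousands of iterations.
* **Convergence.** Relative change in observed-data log-likelihood below
  `tol` (default `1e-7`, `max_iter` 500); for the frailty model the
  $\Psi$ path must additionally have stabilised, because the likelihood
  flattens before $\Psi$ settles.
* **Initialisation.** Incidence from a logistic fit of the raw event
  indicator, latency from a plain Cox fit. EM is initialisation-sensitive;
  these starts are the conventional ones.

**Zero-tail constraint.** The nonparametric latency tail is not identified
beyond the largest event time; by default $S_u$ is set to 0 there, which
sends the uncured-posterior of subjects censored on the plateau to 0. The
flag `zero_tail` exposes the choice.

**Standard errors** are nonparametric bootstrap over subjects (`B = 100`
by default when requested). Fits default to `se = "none"` so that
simulation loops and the bootstrap itself can reuse the fitter cheaply;
`run_pipeline()` requests bootstrap SEs explicitly. The Wald tables then
report $e^{\hat\beta}$ with $\exp(\hat\beta \pm 1.96\,\widehat{SE})$
intervals — the 1.96 normal quantile, which back-computation shows is the
rule behind the published reference tables. The frailty component's
significance is assessed by a likelihood-ratio test against the nested
non-frailty model referred to a 50:50 mixture of $\chi^2_0$ and
$\chi^2_1$, the usual boundary correction; a profile-style check of
$\Psi$ at fixed values is available through `fix_psi`.

## Diagnostics

* `kaplan_meier()` / `plateau_length()`: the product-limit estimate and
  the terminal flat stretch from the last event to the last observation —
  the visual cure signature.
* `maller_zhou_test()`: the cure fraction is estimated by
  $\hat S_{KM}(t^*)$ at the largest event time $t^*$; significance against
  zero uses a one-sided normal test with the Greenwood variance (the
  classical account gives no single test statistic for this step, so the
  normal approximation is documented as this package's operational
  choice). When the terminal plateau carries only $k$ censored subjects
  the raw statistic degenerates to roughly $\sqrt{k}$, so the estimate is
  first discounted by one plateau subject's share ($\hat q(1 - 1/k)$) — a
  continuity correction that restores size control in null simulations
  without measurably affecting power when a real plateau is present. Sufficient follow-up is summarised by $N_n$, the number of
  uncensored times in $(2t^* - t_n, t^*]$, and $\alpha_n = N_n/n$.
* `loglog_survival_check()`: per-stratum $\ln(-\ln \hat S_{KM})$ on the
  common event-time grid where both estimates are strictly inside
  $(0, 1)$. Under proportional hazards the curves are parallel with
  vertical gap $\log HR$. The gap statistics additionally trim times where
  either stratum's survival is outside $[0.02, 0.98]$, because the double
  log amplifies Kaplan–Meier noise without bound in the tails; the
  diagnostic is descriptive (gap range, sign change), not a formal test —
  Schoenfeld-residual tests are deliberately not provided since they are
  not valid in the presence of a cure fraction.
* `compute_vif()`: collinearity by $1/(1-R^2_j)$ from linear regressions
  among the covariates, with exact collinearity flagged rather than
  raised.
* `impute_missing()`: binary covariates with missing values are completed
  by logistic-regression draws given the fully observed covariates plus
  time and event — the natural "multiple regression" scheme for binary
  data; the default of `m = 5` imputations is a convention, not a derived
  quantity. Outcome variables (time, event) are never imputed; rows with
  invalid outcomes are rejected at read time.

## Model evaluation: the K-index

The concordance measure for cure models is implemented as pair-based
concordance on predicted population mortality risk: over pairs
$(i, j)$ with $t_i < t_j$ and $\delta_i = 1$, the proportion in which
$1 - S_{pop}(t_i \mid X_i, Z_i) > 1 - S_{pop}(t_i \mid X_j, Z_j)$, ties
counting one half. This is the package's operational definition (the
upstream estimator it emulates is not specified in enough detail to copy);
it is invariant under strictly increasing transforms of the risk score and
equals 0.5 for a covariate-free model. `compare_models()` reports the
K-index and log-likelihood per model and names the preferred model.

## The synthetic cohort generator

The registry that motivates the package is not public, so every
downstream stage is exercised on synthetic cohorts with known ground
truth. `default_hiv_config()` encodes the published study conditions:
$n = 2170$; ten independent Bernoulli covariates at the published
marginal prevalences (e.g. male 0.835, ART 0.457, IDU transmission
0.671); incidence and latency coefficients set to the published
mixture-cure-frailty estimates; $\Psi = 0.380$. Two quantities the
publication does not determine were fixed once as follows:

* **Baseline hazard**: Weibull with shape 1.2 and scale 40 months, placing
  the uncured marginal median death time at a few tens of months — the
  order implied by the published Kaplan–Meier time scale (follow-up to
  about 250 months, terminal plateau from about 100 months).
* **Censoring**: uniform staggered entry over a 252-month (1998–2019)
  study window plus light exponential dropout (0.001/month).
  `calibrate_censoring()` rescales the window by bisection until the
  Monte-Carlo censoring fraction matches the published 57.5%; cured
  subjects are always censored, so the expected cure fraction is a hard
  floor on achievable censoring and unattainable targets raise an error.

Event times are drawn exactly by inverting the conditional cumulative
hazard, $t = H_0^{-1}\{-\log U / (w\, e^{\beta^\top X})\}$, which is
closed-form for the Weibull and exponential baselines offered. Cured
subjects carry an infinite latent time and are observed at their
censoring time.

What the generator does *not* emulate: dependence among covariates (only
marginals are published; an independence copula is the default and the
schema would admit a correlated generator), calendar-time epidemic
dynamics, and the registry's true entry-time distribution (the published
mean/median follow-up cannot pin it down). Passing tests therefore
validate the estimation machinery under the published design, not the
joint distribution of the real cohort.

## Numerical choices and degenerate inputs

* Ties in the partial likelihood: Breslow approximation, consistent with
  the Breslow baseline update.
* E-step guards: $\pi = 0$ gives posterior 0 (no 0/0); survival factors
  are floored at `1e-300` inside logs.
* $\Psi$ collapsing to the lower bracket is reported as a boundary fit
  with a warning and is numerically identical to the non-frailty model
  (agreement within $10^{-3}$ per coefficient is a tested invariant).
* Exact collinearity in the VIF yields an `Inf` flag; a death recorded
  for a subject declared cured contributes $-\infty$ to the
  complete-data likelihood with a warning; cohorts with zero events are
  refused by the fitters and the pipeline.
* Logistic separation (any incidence coefficient beyond 15 in absolute
  value) sets a `separation` flag on the fit.

## Problem sizes in the shipped checks

The validation suites run on one CPU, so simulation designs are scaled to
keep the full run in minutes while preserving their statistical meaning:
coefficient-recovery coverage uses 10 replicates of $n = 800$ with
$B = 20$ bootstrap resamples; frailty-variance recovery uses 50
replicates of $n = 2000$; Maller–Zhou size and power use 200 replicates
of $n = 2000$; the K-index ordering uses 50 cohorts at the reference
size $n = 2170$, with differences below the EM convergence noise
($10^{-4}$) treated as ties — when $\hat\Psi$ collapses to the boundary
the two fits are the same model and the sign of a $10^{-5}$ K-index
difference is stopping noise, not discrimination. The acceptance script
reports replicate means at the full $n = 2170$.

## Known limitations

* $\Psi$ is weakly identified under the reference design (heavy censoring
  plus a large cured fraction): the profile log-likelihood in $\Psi$ is
  nearly flat over $[0, 0.4]$ on many replicates, so individual
  $\hat\Psi$ draws scatter widely with skew toward the boundary and
  replicate means at $n \approx 2000$ sit below the generating 0.380.
  This is a property of the design, not of the optimiser — forcing
  $\Psi$ to the generating value yields a *lower* observed likelihood on
  such replicates, and the estimator is consistent at larger $n$.
* The latency baseline is strictly nonparametric; parametric (e.g.
  Weibull) latency is available only in the generator, not the fitter.
* Time-varying covariates are not supported; the cumulative-hazard
  notation admits them, but all fitting uses baseline covariates.
* The published K-index values (0.65 vs 0.62) belong to the non-public
  registry; only the model ordering is checkable, and it is checked on
  synthetic cohorts.
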