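# Builders and independent oracles shared across the test files.

# minimal cohort with a single covariate (defaults to alternating 0/1)
toy_cohort <- function(times, events, x = rep_len(0:1, length(times))) {
  cohort(data.frame(subject_id = seq_along(times), time = times,
                    event = events, x = x))
}

# hand-coded product-limit estimator, independent of survival::survfit:
# deaths processed before censorings at tied times
km_oracle <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (k in seq_along(ut)) {
    at_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}

# one-covariate generator config for focused simulations
simple_config <- function(n, intercept, beta_x = 0, theta_x = 0,
                          rate = 0.05, psi = 0,
                          horizon = 400, accrual = 0, dropout = 0,
                          prev = 0.5) {
  generator_config(
    n = n, prevalences = c(x = prev),
    theta = c(intercept = intercept, x = theta_x),
    beta = c(x = beta_x),
    baseline = list(family = "exponential", rate = rate),
    psi = psi,
    censoring = list(horizon = horizon, accrual = accrual,
                     dropout_rate = dropout))
}

# quadrature posterior frailty moments: posterior density proportional to
# f(w; psi) * w^delta * exp(-w * H)
quad_posterior_moments <- function(psi, H, delta) {
  dens <- function(w) gamma_frailty_density(w, psi) * w^delta * exp(-w * H)
  z <- integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  m <- integrate(function(w) w * dens(w), 0, Inf, rel.tol = 1e-10)$value / z
  ml <- integrate(function(w) log(w) * dens(w), 0, Inf, rel.tol = 1e-10)$value / z
  list(mean = m, mean_log = ml)
}
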