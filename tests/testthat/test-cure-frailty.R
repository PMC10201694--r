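test_that("gamma frailty density has unit mean, variance psi and integrates to 1", {
  w <- seq(0.1, 3, by = 0.3)
  expect_equal(gamma_frailty_density(w, 1), exp(-w))  # psi = 1: standard exponential
  for (psi in c(0.1, 0.38, 2)) {
    expect_equal(integrate(gamma_frailty_density, 0, Inf, psi = psi,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  }
  m <- integrate(function(w) w * gamma_frailty_density(w, 0.38), 0, Inf,
                 rel.tol = 1e-10)$value
  m2 <- integrate(function(w) w^2 * gamma_frailty_density(w, 0.38), 0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(m, 1, tolerance = 1e-8)
  expect_equal(m2 - m^2, 0.38, tolerance = 1e-8)
  expect_error(gamma_frailty_density(1, 0), "psi")
})

test_that("marginal uncured survival equals the frailty-integrated survival", {
  expect_equal(marginal_uncured_survival(1, 1), 0.5)
  expect_equal(marginal_uncured_survival(1e-8, 2), exp(-2), tolerance = 1e-6)
  for (H in c(0.5, 1, 2)) {
    quad <- integrate(function(w) exp(-w * H) * gamma_frailty_density(w, 0.38),
                      0, Inf, rel.tol = 1e-12)$value
    expect_equal(marginal_uncured_survival(0.38, H), quad, tolerance = 1e-8)
  }
})

test_that("frailty posterior moments match quadrature", {
  expect_equal(frailty_posterior_moments(0.7, 0, 0)$mean, 1)  # prior unchanged
  expect_equal(frailty_posterior_moments(1, 1, 0)$mean, 0.5)
  set.seed(15)
  for (k in 1:10) {
    psi <- runif(1, 0.05, 2); H <- runif(1, 0, 4); delta <- rbinom(1, 1, 0.5)
    got <- frailty_posterior_moments(psi, H, delta)
    want <- quad_posterior_moments(psi, H, delta)
    expect_equal(got$mean, want$mean, tolerance = 1e-8)
    expect_equal(got$mean_log, want$mean_log, tolerance = 1e-6)
  }
  expect_equal(frailty_posterior_moments(0, c(1, 2), c(0, 1)),
               list(mean = c(1, 1), mean_log = c(0, 0)))
})

test_that("complete-data log-likelihood matches an independent evaluation", {
  # cured subject contributes log(1 - pi) exactly
  ch <- cohort(data.frame(subject_id = 1, time = 1, event = 0, x = 0))
  params <- list(theta = c(intercept = 0.3, x = 0), beta = c(x = 0),
                 baseline = list(time = 0.5, hazard = 1), psi = 1)
  expect_equal(complete_data_loglik(params, ch, v = 0, w = 1),
               log(1 - plogis(0.3)))

  # uncured censored, psi = 1, H = 1, w = 1, pi ~ 1: log(e^-1 * e^-1) = -2
  params$theta <- c(intercept = 40, x = 0)
  expect_equal(complete_data_loglik(params, ch, v = 1, w = 1), -2,
               tolerance = 1e-10)

  # a death for a declared-cured subject is a contradiction
  chd <- cohort(data.frame(subject_id = 1, time = 0.5, event = 1, x = 0))
  expect_warning(ll <- complete_data_loglik(params, chd, v = 0, w = 1),
                 "v = 0")
  expect_equal(ll, -Inf)

  # 20 random subjects against a term-by-term re-implementation
  cfg <- simple_config(n = 20, intercept = 0.5, beta_x = 0.4, rate = 0.05,
                       psi = 0.5, horizon = 60, accrual = 20)
  sim <- simulate_cohort(cfg, seed = 25)
  d <- sim$cohort$data
  ev <- sort(unique(d$time[d$event == 1]))
  params <- list(theta = c(intercept = 0.2, x = -0.3), beta = c(x = 0.4),
                 baseline = list(time = ev, hazard = rep(0.08, length(ev))),
                 psi = 0.38)
  v <- pmax(sim$truth$v, d$event)
  w <- ifelse(v == 1, pmax(sim$truth$w, 0.05), 1)
  ll <- complete_data_loglik(params, sim$cohort, v, w)
  # independent evaluation with dgamma and explicit sums
  ref <- 0
  for (i in seq_len(nrow(d))) {
    pi_i <- plogis(0.2 - 0.3 * d$x[i])
    if (v[i] == 0) { ref <- ref + log(1 - pi_i); next }
    H0 <- sum(params$baseline$hazard[ev <= d$time[i]])
    dh <- ifelse(d$time[i] %in% ev, 0.08, 0)
    eta <- 0.4 * d$x[i]
    Gi <- dgamma(w[i], shape = 1 / 0.38, scale = 0.38) *
      (w[i] * dh * exp(eta))^d$event[i] * exp(-w[i] * H0 * exp(eta))
    ref <- ref + log(pi_i * Gi)
  }
  expect_equal(ll, ref, tolerance = 1e-12)
})

test_that("cumulative hazard is a step PH functional", {
  lat <- list(coefficients = c(x1 = 0.5, x2 = -0.2),
              baseline = list(time = c(1, 3, 7), hazard = c(0.1, 0.2, 0.3)))
  X <- c(x1 = 1, x2 = 1)
  expect_equal(cumulative_hazard(lat, X, 0), 0)
  lat0 <- lat; lat0$coefficients[] <- 0
  expect_equal(cumulative_hazard(lat0, X, c(2, 7, 10)), c(0.1, 0.6, 0.6))
  expect_equal(cumulative_hazard(lat, X, 5),
               0.3 * exp(0.3))
  # doubling via a covariate scales H by exp(beta)
  expect_equal(cumulative_hazard(lat, c(x1 = 1, x2 = 0), 5) /
                 cumulative_hazard(lat, c(x1 = 0, x2 = 0), 5), exp(0.5))
})

test_that("frailty fit at forced psi -> 0 matches the PH mixture cure fit", {
  cfg <- default_hiv_config(n = 700)
  cfg$psi <- 0
  sim <- simulate_cohort(cfg, seed = 33)
  ph <- fit_mixture_cure_ph(sim$cohort, tol = 1e-9)
  fr <- fit_mixture_cure_frailty(sim$cohort, tol = 1e-9, fix_psi = 1e-8)
  expect_true(all(abs(ph$incidence$coefficients -
                        fr$incidence$coefficients) < 1e-3))
  expect_true(all(abs(ph$latency$coefficients -
                        fr$latency$coefficients) < 1e-3))
  expect_true(all(diff(fr$loglik_trace) > -1e-8 * (abs(fr$loglik) + 1)))
})

test_that("frailty variance shrinks to the boundary on frailty-free data", {
  hits <- 0
  for (rep in 1:6) {
    cfg <- simple_config(n = 2000, intercept = 0.4, beta_x = 0.5, rate = 0.04,
                         psi = 0, horizon = 250, accrual = 150)
    sim <- simulate_cohort(cfg, seed = 100 + rep)
    fit <- suppressWarnings(fit_mixture_cure_frailty(sim$cohort))
    if (fit$psi <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("the frailty model nests the non-frailty model in log-likelihood", {
  cfg <- default_hiv_config(n = 700)
  sim <- simulate_cohort(cfg, seed = 37)
  ph <- fit_mixture_cure_ph(sim$cohort)
  fr <- fit_mixture_cure_frailty(sim$cohort)
  expect_gte(fr$loglik, ph$loglik - 1e-3)
  lrt <- frailty_lrt(fr, ph)
  expect_gte(lrt$lr_statistic, 0)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  # population survival is nonincreasing and bounded below by 1 - pi
  nd <- sim$cohort$data[1, covariate_names(sim$cohort)]
  ts <- seq(0, max(sim$cohort$data$time), length.out = 50)
  sp <- population_survival(fr, nd, ts)
  expect_true(all(diff(sp) <= 1e-12))
  expect_true(all(sp >= cure_probability(fr, nd) - 1e-12))
})
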