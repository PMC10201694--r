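test_that("E-step posteriors follow the mixture algebra", {
  # baseline with a single step of log 2 at t = 1 gives S_u(1) = 0.5 when
  # beta = 0; with pi = 0.5 the censored posterior is 0.25 / 0.75 = 1/3
  ch <- cohort(data.frame(subject_id = 1:3, time = c(1, 1, 5),
                          event = c(1, 0, 0), x = 0))
  baseline <- list(time = 1, hazard = log(2))
  g <- e_step_uncured(ch, b = c(intercept = 0, x = 0), beta = c(x = 0),
                      baseline = baseline, zero_tail = TRUE)
  expect_equal(g[1], 1)            # deaths are uncured by definition
  expect_equal(g[2], 1 / 3)
  expect_equal(g[3], 0)            # censored beyond the last event time

  # pi = 0 guard: posterior 0, no 0/0
  g0 <- e_step_uncured(ch, b = c(intercept = -Inf, x = 0), beta = c(x = 0),
                       baseline = baseline, zero_tail = FALSE)
  expect_equal(g0[2:3], c(0, 0))
})

test_that("population survival and cure probability obey the mixture identities", {
  cfg <- simple_config(n = 400, intercept = 0.3, beta_x = 0.5, rate = 0.03,
                       horizon = 150, accrual = 50)
  sim <- simulate_cohort(cfg, seed = 7)
  fit <- fit_mixture_cure_ph(sim$cohort)
  nd <- c(x = 1)
  expect_equal(population_survival(fit, nd, 0), 1)

  # forcing pi(Z) = 0 gives survival 1 at every t; pi = 1 gives S_u itself
  fit0 <- fit; fit0$incidence$coefficients <- c(intercept = -50, x = 0)
  ts <- c(0, 5, 20, 80)
  expect_equal(population_survival(fit0, nd, ts), rep(1, 4))
  fit1 <- fit; fit1$incidence$coefficients <- c(intercept = 50, x = 0)
  H <- cumulative_hazard(fit$latency, nd, ts)
  expect_equal(population_survival(fit1, nd, ts),
               ifelse(ts > fit$max_event_time, 0, exp(-H)),
               tolerance = 1e-12)

  expect_equal(cure_probability(fit1, nd), 1 - plogis(50 + fit1$incidence$coefficients["x"]),
               ignore_attr = TRUE)
  fit2 <- fit; fit2$incidence$coefficients <- c(intercept = 0, x = 0)
  expect_equal(unname(cure_probability(fit2, nd)), 0.5)
  # evaluated at the published frailty-model intercept
  fit2$incidence$coefficients <- c(intercept = 0.544, x = 0)
  expect_equal(unname(cure_probability(fit2, c(x = 0))), 0.3672576,
               tolerance = 1e-6)
})

test_that("with no cured subjects the EM reduces to a plain Cox fit", {
  cfg <- generator_config(
    n = 1200, prevalences = c(x1 = 0.5, x2 = 0.3),
    theta = c(intercept = 30, x1 = 0, x2 = 0),
    beta = c(x1 = 0.6, x2 = -0.4),
    baseline = list(family = "weibull", shape = 1.2, scale = 25),
    psi = 0,
    censoring = list(horizon = 90, accrual = 40, dropout_rate = 0.003))
  sim <- simulate_cohort(cfg, seed = 51)
  fit <- fit_mixture_cure_ph(sim$cohort)
  cx <- survival::coxph(survival::Surv(time, event) ~ x1 + x2,
                        data = sim$cohort$data)
  se <- sqrt(diag(vcov(cx)))
  expect_true(all(abs(fit$latency$coefficients - coef(cx)) < 2 * se))
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * (abs(fit$loglik) + 1)))
})

test_that("censored posteriors decrease with follow-up time under zero-tail", {
  cfg <- simple_config(n = 800, intercept = 0.4, rate = 0.04,
                       horizon = 250, accrual = 200, prev = 0.5)
  sim <- simulate_cohort(cfg, seed = 61)
  fit <- fit_mixture_cure_ph(sim$cohort)
  d <- sim$cohort$data
  for (val in 0:1) {
    cens <- which(d$event == 0 & d$x == val)
    ord <- order(d$time[cens])
    expect_true(all(diff(fit$posteriors[cens][ord]) < 1e-12))
  }
  expect_true(all(fit$posteriors >= 0 & fit$posteriors <= 1))
  expect_true(all(fit$posteriors[d$event == 1] == 1))
  # baseline increments only at observed event times
  expect_true(all(fit$latency$baseline$time %in% d$time[d$event == 1]))
})

test_that("weighted baseline reduces to Nelson-Aalen at beta = 0", {
  set.seed(9)
  times <- sample(1:25, 120, replace = TRUE)
  delta <- rbinom(120, 1, 0.5)
  w <- runif(120, 0.2, 1)
  bl <- curefrail:::breslow_increments(times, delta, w, rep(1, 120))
  # hand-computed weighted Nelson-Aalen increments
  for (k in seq_along(bl$time)) {
    tk <- bl$time[k]
    expect_equal(bl$hazard[k],
                 sum(w[delta == 1 & times == tk]) / sum(w[times >= tk]),
                 tolerance = 1e-12)
  }
})

test_that("EM attains the brute-force maximum on a tiny cohort", {
  cfg <- generator_config(
    n = 24, prevalences = c(x1 = 0.5, x2 = 0.4),
    theta = c(intercept = 0.5, x1 = 0.4, x2 = -0.4),
    beta = c(x1 = 0.5, x2 = -0.5),
    baseline = list(family = "exponential", rate = 0.05),
    psi = 0,
    censoring = list(horizon = 80, accrual = 30, dropout_rate = 0))
  sim <- simulate_cohort(cfg, seed = 71)
  ch <- sim$cohort
  fit <- fit_mixture_cure_ph(ch, tol = 1e-10)
  d <- ch$data
  ev_times <- sort(unique(d$time[d$event == 1]))
  Z <- as.matrix(d[, c("x1", "x2")])
  obj <- function(par) {
    b <- par[1:3]; beta <- par[4:5]; dh <- exp(par[5 + seq_along(ev_times)])
    bl <- list(time = ev_times, hazard = dh)
    pi_u <- plogis(b[1] + Z %*% b[2:3])
    eta <- as.vector(Z %*% beta)
    -curefrail:::observed_loglik(pi_u, eta, bl, d$time, d$event,
                                 zero_tail = TRUE)
  }
  # direct maximisation from a neutral start, independent of the EM path
  start <- c(0, 0, 0, 0, 0, rep(log(1 / length(ev_times)), length(ev_times)))
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-12))
  opt <- optim(opt$par, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_gte(fit$loglik, -opt$value - 1e-4)
})

test_that("bootstrap standard errors are reproducible and positive", {
  cfg <- simple_config(n = 250, intercept = 0.4, beta_x = 0.5, rate = 0.04,
                       horizon = 200, accrual = 100)
  sim <- simulate_cohort(cfg, seed = 81)
  a <- bootstrap_se(sim$cohort, "cure_ph", B = 8, seed = 5)
  b <- bootstrap_se(sim$cohort, "cure_ph", B = 8, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$incidence_se > 0))
  expect_true(all(a$latency_se > 0))
  expect_lte(a$n_dropped, 2)
})
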