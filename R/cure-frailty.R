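#' Gamma frailty density with unit mean
#'
#' Density of the Gamma(1/psi, scale psi) frailty distribution,
#' f(w) = w^(1/psi - 1) exp(-w/psi) / (Gamma(1/psi) psi^(1/psi)),
#' which has mean 1 and variance psi. At psi = 1 it reduces to the
#' standard exponential density.
#'
#' @param w positive frailty value(s).
#' @param psi frailty variance (> 0).
#' @return Density value(s).
#' @export
gamma_frailty_density <- function(w, psi) {
  if (any(psi <= 0)) stop("frailty variance psi must be > 0")
  if (any(w <= 0)) stop("frailty w must be > 0")
  exp((1 / psi - 1) * log(w) - w / psi - lgamma(1 / psi) - log(psi) / psi)
}

#' Subject-specific cumulative hazard of the latency model
#'
#' H_i(t) = integral of h0(s) exp(X' beta) ds over (0, t]; with the step
#' (Breslow) baseline this is the sum of baseline increments at event times
#' <= t, scaled by exp(beta' X) (baseline covariates, no time variation).
#'
#' @param latency latency component of a `cure_fit` (fields `coefficients`,
#'   `baseline`), or any list with those fields.
#' @param X named vector or one-row data.frame of latency covariates.
#' @param t vector of times (>= 0).
#' @return Vector of cumulative hazards.
#' @export
cumulative_hazard <- function(latency, X, t) {
  stopifnot(all(t >= 0))
  beta <- latency$coefficients
  Xr <- extract_row(X, names(beta))
  eta <- as.vector(Xr %*% beta)[1]
  cumhaz_at(latency$baseline, t) * exp(eta)
}

#' Marginal (frailty-integrated) uncured survival
#'
#' Integrating exp(-w H) over the Gamma(1/psi, scale psi) frailty yields
#' (1 + psi H)^(-1/psi); the psi -> 0 limit is exp(-H).
#'
#' @param psi frailty variance (>= 0).
#' @param H cumulative hazard value(s).
#' @return Survival probabilities.
#' @export
marginal_uncured_survival <- function(psi, H) {
  stopifnot(psi >= 0, all(H >= 0))
  uncured_survival(H, psi)
}

#' Posterior moments of the frailty given survival data
#'
#' For an uncured subject with event indicator delta and cumulative hazard
#' H at the observed time, gamma conjugacy gives the posterior
#' w | uncured, data ~ Gamma(1/psi + delta, scale psi / (1 + psi H)), so
#' E[w] = (1 + psi delta) / (1 + psi H) and
#' E[log w] = digamma(1/psi + delta) + log(psi / (1 + psi H)).
#'
#' @param psi frailty variance; psi <= 0 returns the degenerate w = 1
#'   (mean 1, mean log 0).
#' @param H cumulative hazard(s) at the observed time(s).
#' @param delta event indicator(s).
#' @return A list with vectors `mean` and `mean_log`.
#' @export
frailty_posterior_moments <- function(psi, H, delta) {
  if (psi <= 1e-12) {
    return(list(mean = rep(1, length(H)), mean_log = rep(0, length(H))))
  }
  list(mean = (1 + psi * delta) / (1 + psi * H),
       mean_log = digamma(1 / psi + delta) + log(psi / (1 + psi * H)))
}

#' Complete-data log-likelihood of the mixture cure frailty model
#'
#' Evaluates sum_i log L_{i,c} with
#' L_{i,c} = (1 - pi_i)^(1 - v_i) (pi_i G_i)^(v_i) and
#' G_i = f(w_i; psi) [w_i h0(t_i) exp(X' beta)]^delta_i exp(-w_i H_i(t_i)),
#' where f is the unit-mean gamma frailty density and h0, H0 come from the
#' step baseline (h0(t_i) is the increment at t_i). A death recorded for a
#' subject declared cured (delta = 1, v = 0) is a contradiction and
#' contributes -Inf, with a warning.
#'
#' @param params list with `theta` (incidence coefficients incl.
#'   `intercept`), `beta`, `baseline` (`list(time, hazard)`), `psi` (> 0).
#' @param ch a [cohort()].
#' @param v 0/1 vector of latent uncured indicators.
#' @param w positive frailty values (used where v = 1).
#' @return The complete-data log-likelihood (scalar).
#' @export
complete_data_loglik <- function(params, ch, v, w) {
  stopifnot(all(v %in% c(0, 1)), all(w[v == 1] > 0), params$psi > 0)
  dm <- design_matrices(ch)
  pi_u <- stats::plogis(incidence_lp(params$theta, dm$Z))
  eta <- as.vector(dm$X[, names(params$beta), drop = FALSE] %*% params$beta)
  H <- cumhaz_at(params$baseline, dm$time) * exp(eta)
  dh <- increment_at(params$baseline, dm$time)
  ll <- numeric(length(v))
  cured <- v == 0
  ll[cured] <- log(pmax(1 - pi_u[cured], 1e-300))
  u <- !cured
  if (any(dm$delta == 1 & cured)) {
    warning("death recorded for a subject with v = 0; -Inf contribution")
    ll[dm$delta == 1 & cured] <- -Inf
  }
  if (any(u)) {
    lg <- log(gamma_frailty_density(w[u], params$psi))
    haz <- dm$delta[u] * (log(pmax(w[u] * dh[u] * exp(eta[u]), 1e-300)))
    ll[u] <- log(pmax(pi_u[u], 1e-300)) + lg + haz - w[u] * H[u]
  }
  sum(ll)
}

#' Fit the mixture cure frailty model by EM
#'
#' Logistic incidence, PH latency with a nonparametric Breslow baseline and
#' a subject-level gamma frailty w ~ Gamma(1/psi, scale psi) (mean 1,
#' variance psi) multiplying the hazard of uncured subjects. The frailty is
#' integrated out analytically via gamma conjugacy: the E-step needs only
#' E[v_i], E[w_i | uncured] and E[log w_i | uncured]; the M-step updates
#' the incidence coefficients by weighted logistic regression, (beta, H0)
#' by a posterior-weighted Cox partial likelihood with offset
#' log E[w_i] plus a Breslow baseline update, and psi by a bracketed
#' one-dimensional profile maximisation of the observed-data
#' log-likelihood on [1e-8, 50] given the other parameters.
#'
#' @inheritParams fit_mixture_cure_ph
#' @param psi_init starting frailty variance (default 0.5).
#' @param fix_psi optional fixed value of psi (skips the psi update); use a
#'   tiny value such as 1e-8 to force the non-frailty limit.
#' @return An object of class `c("cure_frailty_fit", "cure_fit")`: fields
#'   of a PH cure fit plus `psi`, `psi_se`, `psi_ci`, `boundary` (TRUE when
#'   psi collapsed to the lower bracket, i.e. no detectable frailty) and
#'   posteriors `E_w`, `E_logw`.
#' @export
fit_mixture_cure_frailty <- function(ch, tol = 1e-7, max_iter = 500,
                                     zero_tail = TRUE, psi_init = 0.5,
                                     fix_psi = NULL,
                                     se = c("none", "bootstrap"), B = 100,
                                     seed = 1L) {
  se <- match.arg(se)
  stopifnot(inherits(ch, "cohort"))
  if (n_events(ch) < 1) stop("model fitting requires at least one event")
  dm <- design_matrices(ch)
  time <- dm$time; delta <- dm$delta
  psi_lo <- 1e-8; psi_hi <- 50

  theta <- weighted_logistic(delta, dm$Z)
  cx <- suppressWarnings(
    survival::coxph(survival::Surv(time, delta) ~ dm$X, ties = "breslow"))
  beta <- sanitize_coef(stats::setNames(stats::coef(cx), colnames(dm$X)))
  eta <- as.vector(dm$X %*% beta)
  baseline <- breslow_increments(time, delta, rep(1, length(time)), exp(eta))
  psi <- if (is.null(fix_psi)) psi_init else max(fix_psi, psi_lo)

  trace <- numeric(0)
  ll_old <- -Inf
  psi_old <- psi
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step
    H <- cumhaz_at(baseline, time) * exp(eta)
    g <- e_step_uncured(ch, theta, beta, baseline, zero_tail = zero_tail,
                        psi = psi)
    mom <- frailty_posterior_moments(psi, H, delta)
    Ew <- mom$mean; Elogw <- mom$mean_log

    # M-step
    theta <- weighted_logistic(g, dm$Z)
    keep <- g > 1e-10
    cx <- suppressWarnings(
      survival::coxph(survival::Surv(time[keep], delta[keep]) ~
                        dm$X[keep, , drop = FALSE] +
                        offset(log(Ew[keep])),
                      weights = g[keep], ties = "breslow",
                      init = beta,
                      control = survival::coxph.control(iter.max = 50)))
    beta <- sanitize_coef(stats::setNames(stats::coef(cx), colnames(dm$X)))
    eta <- as.vector(dm$X %*% beta)
    baseline <- breslow_increments(time, delta, g, Ew * exp(eta))
    pi_u <- stats::plogis(incidence_lp(theta, dm$Z))
    if (is.null(fix_psi)) {
      # profile update: maximise the observed-data log-likelihood in psi
      # given the other parameters (monotone coordinate ascent with the
      # same fixed point as the expected-complete-data update, but without
      # the damped EM rate near the optimum/boundary)
      opt <- stats::optimize(function(lp)
        observed_loglik(pi_u, eta, baseline, time, delta, psi = exp(lp),
                        zero_tail = zero_tail),
        interval = log(c(psi_lo, psi_hi)), maximum = TRUE, tol = 1e-10)
      psi <- exp(opt$maximum)
    }

    ll <- observed_loglik(pi_u, eta, baseline, time, delta, psi = psi,
                          zero_tail = zero_tail)
    trace <- c(trace, ll)
    # the likelihood flattens long before psi settles, so convergence
    # additionally requires the frailty variance path to stabilise
    psi_stable <- !is.null(fix_psi) ||
      abs(psi - psi_old) < 1e-5 + 1e-3 * psi_old
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1) &&
        psi_stable) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    psi_old <- psi
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")

  H <- cumhaz_at(baseline, time) * exp(eta)
  g <- e_step_uncured(ch, theta, beta, baseline, zero_tail = zero_tail,
                      psi = psi)
  mom <- frailty_posterior_moments(psi, H, delta)
  boundary <- is.null(fix_psi) && psi < 1e-6
  if (boundary) {
    warning("frailty variance collapsed to the boundary (psi ~ 0); ",
            "fit is equivalent to the non-frailty mixture cure model")
  }
  fit <- structure(list(
    incidence = list(coefficients = theta, se = NULL),
    latency = list(coefficients = beta, se = NULL, baseline = baseline,
                   zero_tail = zero_tail),
    psi = psi, psi_se = NULL, psi_ci = NULL, boundary = boundary,
    loglik = trace[length(trace)], loglik_trace = trace,
    n_iter = length(trace), converged = converged,
    posteriors = g, E_w = mom$mean, E_logw = mom$mean_log,
    separation = any(abs(theta) > 15) || any(abs(beta) >= 15),
    n = length(time), n_event = sum(delta),
    max_event_time = max(time[delta == 1]),
    incidence_covariates = ch$schema$incidence,
    latency_covariates = ch$schema$latency,
    model = "cure_frailty"), class = c("cure_frailty_fit", "cure_fit"))
  if (se == "bootstrap") fit <- add_bootstrap_se(fit, ch, B = B, seed = seed)
  fit
}

#' Likelihood-ratio test for the frailty component
#'
#' Compares the frailty fit with the nested psi = 0 (non-frailty) mixture
#' cure fit on the same cohort. Because psi = 0 lies on the boundary of the
#' parameter space, the LR statistic is referred to a 50:50 mixture of a
#' point mass at 0 and chi-squared(1).
#'
#' @param frailty_fit a `cure_frailty_fit`.
#' @param ph_fit the corresponding `cure_ph_fit` on the same cohort; fitted
#'   automatically from `ch` when omitted.
#' @param ch the cohort (needed when `ph_fit` is missing).
#' @return A list: `lr_statistic`, `p_value`.
#' @export
frailty_lrt <- function(frailty_fit, ph_fit = NULL, ch = NULL) {
  stopifnot(inherits(frailty_fit, "cure_frailty_fit"))
  if (is.null(ph_fit)) {
    if (is.null(ch)) stop("supply ph_fit or ch")
    ph_fit <- fit_mixture_cure_ph(ch, zero_tail = frailty_fit$latency$zero_tail)
  }
  lr <- max(0, 2 * (frailty_fit$loglik - ph_fit$loglik))
  p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  list(lr_statistic = lr, p_value = p)
}
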