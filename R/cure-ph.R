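# Shared internals for the mixture-cure EM fitters ---------------------------

design_matrices <- function(ch) {
  d <- ch$data
  Z <- as.matrix(d[, ch$schema$incidence, drop = FALSE])
  X <- as.matrix(d[, ch$schema$latency, drop = FALSE])
  if (anyNA(Z) || anyNA(X)) stop("covariates must be complete; impute first")
  list(Z = Z, X = X, time = d$time, delta = d$event)
}

# Breslow step increments dH0 at unique event times.
# numerator: sum of subject weights over deaths at t_k (weights are the
# posterior uncured probabilities, 1 for deaths); denominator: weighted
# risk-set sum of risk scores (weight * E[w] * exp(beta'X)).
breslow_increments <- function(time, delta, weights, risk_score) {
  ev_times <- sort(unique(time[delta == 1]))
  ord <- order(time)
  t_s <- time[ord]
  rs <- (weights * risk_score)[ord]
  # risk set sum for t >= t_k: reverse cumulative sum
  rev_cum <- rev(cumsum(rev(rs)))
  denom <- rev_cum[findInterval(ev_times, t_s, left.open = TRUE) + 1]
  num <- vapply(ev_times,
                function(tk) sum(weights[delta == 1 & time == tk]),
                numeric(1))
  list(time = ev_times, hazard = num / denom)
}

# cumulative baseline hazard H0(t), right-continuous step function
cumhaz_at <- function(baseline, t) {
  H <- cumsum(baseline$hazard)
  idx <- findInterval(t, baseline$time)
  ifelse(idx == 0, 0, H[pmax(idx, 1)])
}

# hazard increment dH0 at exact times (0 where t is not a step time)
increment_at <- function(baseline, t) {
  m <- match(t, baseline$time)
  out <- rep(0, length(t))
  out[!is.na(m)] <- baseline$hazard[m[!is.na(m)]]
  out
}

# cap diverging coefficients (monotone partial likelihood, e.g. a rare
# covariate whose carriers all die last): beyond +/-15 the fit is not
# numerically identifiable and uncapped values break later coxph inits
sanitize_coef <- function(b, cap = 15) {
  b[!is.finite(b)] <- 0
  pmin(pmax(b, -cap), cap)
}

weighted_logistic <- function(g, Z) {
  df <- as.data.frame(Z)
  fit <- suppressWarnings(stats::glm(g ~ ., data = df,
                                     family = stats::quasibinomial()))
  b <- stats::coef(fit)
  names(b)[1] <- "intercept"
  b
}

incidence_lp <- function(b, Z) {
  b[["intercept"]] + as.vector(Z[, setdiff(names(b), "intercept"),
                                 drop = FALSE] %*%
                                 b[setdiff(names(b), "intercept")])
}

#' E-step posterior probability of being uncured
#'
#' Given incidence coefficients `b`, latency coefficients `beta` and a step
#' baseline cumulative hazard, computes E[v_i | data]: 1 for deaths, and
#' pi S_u(t) / (1 - pi + pi S_u(t)) for censored subjects, where
#' S_u(t) = exp(-H0(t) exp(beta' X)). With the zero-tail constraint, S_u is
#' 0 beyond the largest event time, so subjects censored there get
#' posterior 0.
#'
#' @param ch a [cohort()].
#' @param b named incidence coefficients including `intercept`.
#' @param beta named latency coefficients.
#' @param baseline `list(time, hazard)` of Breslow step increments.
#' @param zero_tail logical; apply the zero-tail constraint (default TRUE).
#' @param psi optional gamma-frailty variance; when > 0 the uncured
#'   survival is the frailty-marginal (1 + psi H)^(-1/psi).
#' @return Numeric vector of posteriors in `[0, 1]`.
#' @export
e_step_uncured <- function(ch, b, beta, baseline, zero_tail = TRUE, psi = 0) {
  dm <- design_matrices(ch)
  pi_u <- stats::plogis(incidence_lp(b, dm$Z))
  eta <- as.vector(dm$X[, names(beta), drop = FALSE] %*% beta)
  H <- cumhaz_at(baseline, dm$time) * exp(eta)
  Su <- uncured_survival(H, psi)
  if (zero_tail && length(baseline$time)) {
    Su[dm$time > max(baseline$time)] <- 0
  }
  g <- ifelse(dm$delta == 1, 1,
              ifelse(pi_u <= 0, 0, pi_u * Su / (1 - pi_u + pi_u * Su)))
  pmin(pmax(g, 0), 1)
}

uncured_survival <- function(H, psi) {
  if (psi > 1e-12) (1 + psi * H)^(-1 / psi) else exp(-H)
}

observed_loglik <- function(pi_u, eta, baseline, time, delta, psi = 0,
                            zero_tail = TRUE) {
  H <- cumhaz_at(baseline, time) * exp(eta)
  Su <- uncured_survival(H, psi)
  if (zero_tail && length(baseline$time)) Su[time > max(baseline$time)] <- 0
  dh <- increment_at(baseline, time)
  if (psi > 1e-12) {
    log_dens <- log(pmax(dh, 1e-300)) + eta - (1 / psi + 1) * log1p(psi * H)
  } else {
    log_dens <- log(pmax(dh, 1e-300)) + eta - H
  }
  ll_death <- log(pmax(pi_u, 1e-300)) + log_dens
  ll_cens <- log(pmax(1 - pi_u + pi_u * Su, 1e-300))
  sum(ifelse(delta == 1, ll_death, ll_cens))
}

#' Fit the semiparametric PH mixture cure model by EM
#'
#' Fits S_pop(t | X, Z) = pi(Z) S(t | X) + 1 - pi(Z), with logistic
#' incidence pi(Z) and a proportional-hazards latency S(t | X) =
#' exp(-H0(t) exp(beta' X)) whose baseline H0 is an unspecified step
#' function estimated by a Breslow-type update. The EM alternates the
#' posterior uncured probabilities (E-step) with a weighted logistic
#' regression for the incidence coefficients and a posterior-weighted Cox
#' partial likelihood (Breslow ties) plus baseline update for the latency
#' part, until the observed-data log-likelihood stabilises.
#'
#' @param ch a [cohort()] with at least one event and complete covariates.
#' @param tol relative log-likelihood convergence tolerance (default 1e-7).
#' @param max_iter maximum EM iterations (default 500).
#' @param zero_tail apply the zero-tail constraint: uncured survival is 0
#'   beyond the largest event time (default TRUE; required for
#'   identifiability of the nonparametric tail).
#' @param se `"none"` or `"bootstrap"`; bootstrap refits `B` resampled
#'   cohorts (see [bootstrap_se()]).
#' @param B bootstrap replicates when `se = "bootstrap"` (default 100).
#' @param seed seed for the bootstrap resampling.
#' @return An object of class `c("cure_ph_fit", "cure_fit")`: `incidence`
#'   (coefficients, se), `latency` (coefficients, se, baseline step
#'   increments, zero_tail), `loglik`, `loglik_trace` (nondecreasing),
#'   `n_iter`, `converged`, `posteriors` (E[v_i], 1 for deaths),
#'   `separation` flag for a degenerate logistic part.
#' @references Standard semiparametric mixture-cure EM estimation as
#'   implemented for logistic/PH cure models.
#' @export
fit_mixture_cure_ph <- function(ch, tol = 1e-7, max_iter = 500,
                                zero_tail = TRUE,
                                se = c("none", "bootstrap"), B = 100,
                                seed = 1L) {
  se <- match.arg(se)
  stopifnot(inherits(ch, "cohort"))
  if (n_events(ch) < 1) stop("model fitting requires at least one event")
  dm <- design_matrices(ch)
  time <- dm$time; delta <- dm$delta

  # initialisation: incidence from a logistic fit of the event indicator,
  # latency from a plain Cox fit (EM is initialisation-sensitive)
  b <- weighted_logistic(delta, dm$Z)
  cx <- suppressWarnings(
    survival::coxph(survival::Surv(time, delta) ~ dm$X, ties = "breslow"))
  beta <- sanitize_coef(stats::setNames(stats::coef(cx), colnames(dm$X)))
  eta <- as.vector(dm$X %*% beta)
  baseline <- breslow_increments(time, delta, rep(1, length(time)), exp(eta))

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pi_u <- stats::plogis(incidence_lp(b, dm$Z))
    g <- e_step_uncured(ch, b, beta, baseline, zero_tail = zero_tail)

    b <- weighted_logistic(g, dm$Z)
    keep <- g > 1e-10
    cx <- suppressWarnings(
      survival::coxph(survival::Surv(time[keep], delta[keep]) ~
                        dm$X[keep, , drop = FALSE],
                      weights = g[keep], ties = "breslow",
                      init = beta,
                      control = survival::coxph.control(iter.max = 50)))
    beta <- sanitize_coef(stats::setNames(stats::coef(cx), colnames(dm$X)))
    eta <- as.vector(dm$X %*% beta)
    baseline <- breslow_increments(time, delta, g, exp(eta))

    pi_u <- stats::plogis(incidence_lp(b, dm$Z))
    ll <- observed_loglik(pi_u, eta, baseline, time, delta,
                          zero_tail = zero_tail)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")

  g <- e_step_uncured(ch, b, beta, baseline, zero_tail = zero_tail)
  fit <- structure(list(
    incidence = list(coefficients = b, se = NULL),
    latency = list(coefficients = beta, se = NULL, baseline = baseline,
                   zero_tail = zero_tail),
    psi = NULL,
    loglik = trace[length(trace)], loglik_trace = trace,
    n_iter = length(trace), converged = converged,
    posteriors = g,
    separation = any(abs(b) > 15) || any(abs(beta) >= 15),
    n = length(time), n_event = sum(delta),
    max_event_time = max(time[delta == 1]),
    incidence_covariates = ch$schema$incidence,
    latency_covariates = ch$schema$latency,
    model = "cure_ph"), class = c("cure_ph_fit", "cure_fit"))
  if (se == "bootstrap") fit <- add_bootstrap_se(fit, ch, B = B, seed = seed)
  fit
}

#' @export
print.cure_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d (%d events), loglik = %.3f, %d EM iterations%s\n",
              if (inherits(x, "cure_frailty_fit"))
                "Mixture cure frailty model" else
                  "Semiparametric PH mixture cure model",
              x$n, x$n_event, x$loglik, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  cat("Incidence (uncured-probability) coefficients:\n")
  print(round(x$incidence$coefficients, 4))
  cat("Latency (hazard) coefficients:\n")
  print(round(x$latency$coefficients, 4))
  if (!is.null(x$psi)) cat(sprintf("Frailty variance psi = %.4f\n", x$psi))
  invisible(x)
}

extract_row <- function(newdata, vars) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  miss <- setdiff(vars, colnames(newdata))
  if (length(miss)) stop("newdata lacks covariate(s): ",
                         paste(miss, collapse = ", "))
  newdata[, vars, drop = FALSE]
}

#' Population survival function of a fitted cure model
#'
#' S_pop(t | X, Z) = pi(Z) S_u(t | X) + 1 - pi(Z). For a frailty fit the
#' uncured survival is the gamma-frailty marginal
#' (1 + psi H(t))^(-1/psi); otherwise exp(-H(t)).
#'
#' @param fit a `cure_fit`.
#' @param newdata named vector or one-row data.frame holding the subject's
#'   covariates (both X and Z are taken from it).
#' @param t vector of times (months, >= 0).
#' @return Vector of survival probabilities, one per element of `t`.
#' @export
population_survival <- function(fit, newdata, t) {
  stopifnot(inherits(fit, "cure_fit"), all(t >= 0))
  Z <- extract_row(newdata, fit$incidence_covariates)
  X <- extract_row(newdata, fit$latency_covariates)
  b <- fit$incidence$coefficients
  pi_u <- stats::plogis(incidence_lp(b, Z))[1]
  beta <- fit$latency$coefficients
  eta <- as.vector(X %*% beta)[1]
  H <- cumhaz_at(fit$latency$baseline, t) * exp(eta)
  psi <- if (is.null(fit$psi)) 0 else fit$psi
  Su <- uncured_survival(H, psi)
  if (fit$latency$zero_tail) Su[t > fit$max_event_time] <- 0
  pi_u * Su + 1 - pi_u
}

#' Probability of cure for a subject profile
#'
#' 1 - exp(Z theta) / (1 + exp(Z theta)) at the fitted incidence
#' coefficients: the estimated probability of never experiencing the event.
#'
#' @param fit a `cure_fit`.
#' @param newdata named vector, matrix or data.frame of covariate profiles
#'   (one row per subject).
#' @return Vector of cure probabilities in `[0, 1]`.
#' @export
cure_probability <- function(fit, newdata) {
  stopifnot(inherits(fit, "cure_fit"))
  Z <- extract_row(newdata, fit$incidence_covariates)
  1 - stats::plogis(incidence_lp(fit$incidence$coefficients, Z))
}

#' Nonparametric bootstrap standard errors for a cure model fit
#'
#' Resamples subjects with replacement, refits the model on each replicate
#' and reports the replicate standard deviation of every coefficient (and
#' of the frailty variance for frailty fits, with a Wald 95% CI).
#' Replicates whose EM fails to converge are dropped and counted.
#' Deterministic under a fixed seed.
#'
#' @param ch a [cohort()].
#' @param model `"cure_ph"` or `"cure_frailty"`.
#' @param B number of bootstrap replicates (>= 2; default 100).
#' @param seed integer seed.
#' @param ... further arguments passed to the fitter (e.g. `tol`,
#'   `zero_tail`).
#' @return A list: `incidence_se`, `latency_se`, `psi_se`, `psi_ci`
#'   (frailty fits only), `B`, `n_dropped`.
#' @export
bootstrap_se <- function(ch, model = c("cure_ph", "cure_frailty"),
                         B = 100, seed = 1L, ...) {
  model <- match.arg(model)
  stopifnot(B >= 2)
  fitter <- if (model == "cure_ph") fit_mixture_cure_ph else
    fit_mixture_cure_frailty
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- n_subjects(ch)
  idx_list <- replicate(B, sample.int(n, n, replace = TRUE), simplify = FALSE)
  reps <- lapply(idx_list, function(idx) {
    d <- ch$data[idx, , drop = FALSE]
    d$subject_id <- seq_len(n)
    chb <- cohort(d, ch$schema)
    if (sum(d$event) == 0) return(NULL)
    f <- tryCatch(suppressWarnings(fitter(chb, se = "none", ...)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NULL)
    c(f$incidence$coefficients, f$latency$coefficients,
      psi = if (is.null(f$psi)) NA_real_ else f$psi)
  })
  ok <- !vapply(reps, is.null, logical(1))
  mat <- do.call(rbind, reps[ok])
  p_inc <- length(ch$schema$incidence) + 1
  p_lat <- length(ch$schema$latency)
  ses <- apply(mat, 2, stats::sd)
  out <- list(incidence_se = ses[seq_len(p_inc)],
              latency_se = ses[p_inc + seq_len(p_lat)],
              B = B, n_dropped = sum(!ok))
  if (model == "cure_frailty") {
    psi_rep <- mat[, "psi"]
    psi_hat <- mean(psi_rep)
    out$psi_se <- stats::sd(psi_rep)
    out$psi_ci <- c(max(0, psi_hat - 1.96 * out$psi_se),
                    psi_hat + 1.96 * out$psi_se)
  }
  out
}

add_bootstrap_se <- function(fit, ch, B, seed) {
  bs <- bootstrap_se(ch,
                     model = if (inherits(fit, "cure_frailty_fit"))
                       "cure_frailty" else "cure_ph",
                     B = B, seed = seed,
                     zero_tail = fit$latency$zero_tail)
  fit$incidence$se <- bs$incidence_se
  names(fit$incidence$se) <- names(fit$incidence$coefficients)
  fit$latency$se <- bs$latency_se
  names(fit$latency$se) <- names(fit$latency$coefficients)
  if (inherits(fit, "cure_frailty_fit")) {
    fit$psi_se <- bs$psi_se
    fit$psi_ci <- c(max(0, fit$psi - 1.96 * bs$psi_se),
                    fit$psi + 1.96 * bs$psi_se)
  }
  fit$bootstrap <- list(B = bs$B, n_dropped = bs$n_dropped)
  fit
}
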