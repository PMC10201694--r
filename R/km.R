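#' Kaplan-Meier product-limit estimate for a cohort
#'
#' Thin wrapper around [survival::survfit()] returning a tidy step-function
#' table. Deaths are processed before censorings at tied times, the
#' product-limit convention.
#'
#' @param ch a [cohort()].
#' @return A data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `std_err` (Greenwood standard error of the survival
#'   estimate). `surv` is nonincreasing and S(0-) = 1.
#' @export
kaplan_meier <- function(ch) {
  stopifnot(inherits(ch, "cohort"))
  d <- ch$data
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                          conf.type = "none")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, surv = sf$surv,
                    std_err = sf$surv * sf$std.err)
  class(out) <- c("km_curve", "data.frame")
  out
}

km_eval <- function(curve, t) {
  # right-continuous step evaluation; S(t) = 1 before the first time point
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1)])
}

#' Terminal plateau of a Kaplan-Meier curve
#'
#' The span from the last event time to the largest observed time — the
#' stretch over which the curve is flat above zero. A long plateau with
#' many censored subjects on it is the visual signature of a cure fraction.
#'
#' @param curve a `km_curve` from [kaplan_meier()].
#' @param horizon optional truncation (months) of the largest observed time.
#' @return A list: `plateau_months`, `has_plateau` (FALSE when the curve
#'   reaches zero, in which case the length is 0), `last_event_time`,
#'   `max_time`, `plateau_level` (KM estimate on the plateau).
#' @export
plateau_length <- function(curve, horizon = Inf) {
  stopifnot(inherits(curve, "km_curve"))
  max_t <- min(max(curve$time), horizon)
  level <- min(curve$surv)
  ev <- curve$time[curve$n_event > 0]
  if (!length(ev)) {
    return(list(plateau_months = max_t, has_plateau = TRUE,
                last_event_time = 0, max_time = max_t, plateau_level = 1))
  }
  last_ev <- max(ev)
  if (level <= 0) {
    return(list(plateau_months = 0, has_plateau = FALSE,
                last_event_time = last_ev, max_time = max_t,
                plateau_level = 0))
  }
  list(plateau_months = max(max_t - last_ev, 0),
       has_plateau = max_t > last_ev,
       last_event_time = last_ev, max_time = max_t, plateau_level = level)
}

#' Maller-Zhou test for the presence of a cure fraction
#'
#' Estimates the cure fraction as the Kaplan-Meier value at the largest
#' event time t*, and tests whether it is significantly above zero with a
#' one-sided normal test based on the Greenwood variance, after a
#' continuity correction that discounts one plateau subject's share of the
#' estimate (without it the normal approximation over-rejects whenever a
#' handful of subjects outlive the last event). Sufficiency of
#' follow-up is summarised by N_n, the number of uncensored times in the
#' interval (2 t* - t_n, t*] with t_n the largest observed time, and
#' alpha_n = N_n / n; follow-up is reported sufficient when the curve has a
#' terminal plateau carrying at least one uncensored time in that interval.
#'
#' @param ch a [cohort()] with at least one event.
#' @param alpha significance level (default 0.05).
#' @return An object of class `maller_zhou`: `estimated_cure_fraction`,
#'   `se` (Greenwood), `statistic`, `p_value`, `reject` (cure fraction
#'   significantly > 0), `n_interval` (N_n), `alpha_n`,
#'   `sufficient_followup`, `alpha`.
#' @export
maller_zhou_test <- function(ch, alpha = 0.05) {
  stopifnot(inherits(ch, "cohort"))
  if (n_events(ch) == 0) stop("Maller-Zhou test undefined with zero events")
  curve <- kaplan_meier(ch)
  d <- ch$data
  t_star <- max(d$time[d$event == 1])
  t_n <- max(d$time)
  q_hat <- km_eval(curve, t_star)
  i_star <- max(which(curve$time <= t_star))
  se <- curve$std_err[i_star]
  lo <- 2 * t_star - t_n
  Nn <- sum(d$event == 1 & d$time > lo & d$time <= t_star)
  # continuity correction: discount one plateau subject's contribution.
  # Without it the normal test reduces to "reject when >= 3 subjects
  # outlive the last event", which grossly over-rejects when the plateau
  # carries only a handful of stragglers.
  k_plateau <- sum(d$event == 0 & d$time >= t_star)
  q_cc <- if (k_plateau > 0) q_hat * (1 - 1 / k_plateau) else 0
  if (q_cc <= 0 || !is.finite(se) || se <= 0) {
    z <- 0; p <- 1
  } else {
    z <- q_cc / se
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  structure(list(estimated_cure_fraction = q_hat, se = se, statistic = z,
                 p_value = p, reject = p < alpha, n_interval = Nn,
                 alpha_n = Nn / nrow(d),
                 sufficient_followup = (t_n > t_star) && Nn >= 1,
                 alpha = alpha),
            class = "maller_zhou")
}

#' @export
print.maller_zhou <- function(x, ...) {
  cat(sprintf("Maller-Zhou cure-fraction test\n  estimated cure fraction: %.4f (SE %.4f)\n",
              x$estimated_cure_fraction, x$se))
  cat(sprintf("  z = %.3f, one-sided p = %.4g -> %s at level %.2f\n",
              x$statistic, x$p_value,
              if (x$reject) "cure fraction > 0" else "no evidence of cures",
              x$alpha))
  cat(sprintf("  N_n = %d, alpha_n = %.4f, sufficient follow-up: %s\n",
              x$n_interval, x$alpha_n, x$sufficient_followup))
  invisible(x)
}

#' ln(-ln S) proportional-hazards diagnostic
#'
#' Computes per-stratum ln(-ln S_KM(t)) for the two levels of a binary
#' covariate, on the common grid of event times where both stratum
#' estimates lie strictly in (0, 1). Under proportional hazards the two
#' transformed curves are parallel with a constant vertical gap equal to
#' the log hazard ratio; the gap range is reported as a descriptive
#' non-parallelism diagnostic (it is not a formal test).
#'
#' @param ch a [cohort()].
#' @param covariate name of a complete binary covariate.
#' @return A list: `curves` (data.frame `time`, `stratum`, `surv`,
#'   `loglog`), `gap` (data.frame `time`, `gap` = stratum-1 minus
#'   stratum-0 loglog), `mean_gap`, `gap_range`, `sign_change` (TRUE when
#'   the gap crosses zero, suggesting crossing hazards).
#' @export
loglog_survival_check <- function(ch, covariate) {
  stopifnot(inherits(ch, "cohort"), covariate %in% covariate_names(ch))
  d <- ch$data
  if (anyNA(d[[covariate]])) stop("covariate must be complete")
  strata <- list()
  for (val in 0:1) {
    ds <- d[d[[covariate]] == val, , drop = FALSE]
    if (!nrow(ds) || sum(ds$event) == 0) {
      warning("stratum ", covariate, "=", val, " has no events; omitted")
      next
    }
    strata[[as.character(val)]] <- kaplan_meier(cohort(ds, ch$schema))
  }
  if (length(strata) < 2) {
    return(list(curves = NULL, gap = NULL, mean_gap = NA_real_,
                gap_range = NA_real_, sign_change = NA))
  }
  grid <- sort(unique(d$time[d$event == 1]))
  svals <- lapply(strata, km_eval, t = grid)
  ok <- Reduce(`&`, lapply(svals, function(s) s > 0 & s < 1))
  # the gap diagnostic additionally trims the extreme tails, where the
  # log(-log) transform amplifies Kaplan-Meier noise without bound
  core <- ok & Reduce(`&`, lapply(svals, function(s) s >= 0.02 & s <= 0.98))
  ll <- lapply(svals, function(s) log(-log(s)))
  curves <- do.call(rbind, lapply(names(strata), function(nm) {
    data.frame(time = grid[ok], stratum = as.integer(nm),
               surv = svals[[nm]][ok], loglog = ll[[nm]][ok])
  }))
  gap <- (ll[["1"]] - ll[["0"]])[core]
  list(curves = curves,
       gap = data.frame(time = grid[core], gap = gap),
       mean_gap = mean(gap),
       gap_range = if (length(gap)) diff(range(gap)) else NA_real_,
       sign_change = any(gap > 0) && any(gap < 0))
}
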