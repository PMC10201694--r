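#' Wald summary row: ratio and 95% confidence interval
#'
#' The transform used by the reported coefficient tables: ratio =
#' exp(coefficient) (an odds ratio for incidence rows, a hazard ratio for
#' latency rows), 95% CI = exp(coefficient +/- 1.96 * SE), and a two-sided
#' normal p-value, displayed to 3 decimals with values below 0.001 shown
#' as 0.001.
#'
#' @param coefficient,se numeric scalars (vectors are recycled elementwise).
#' @param label optional display label.
#' @return A data.frame with `label`, `coefficient`, `se`, `ratio`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
wald_row <- function(coefficient, se, label = NA_character_) {
  ratio <- exp(coefficient)
  data.frame(label = label, coefficient = coefficient, se = se,
             ratio = ratio,
             ci_lower = exp(coefficient - 1.96 * se),
             ci_upper = exp(coefficient + 1.96 * se),
             p_value = ifelse(se > 0,
                              2 * stats::pnorm(-abs(coefficient / se)),
                              ifelse(coefficient == 0, 1, 0)),
             stringsAsFactors = FALSE)
}

#' Coefficient table for a fitted cure model
#'
#' One row per covariate per model part: odds ratios with 95% CIs for the
#' incidence (cure-probability) part, hazard ratios for the latency part,
#' via [wald_row()]. Requires standard errors (bootstrap them first);
#' without SEs the ratios are reported and the CI columns are NA with a
#' note attribute.
#'
#' @param fit a `cure_fit`, ideally with bootstrap SEs attached.
#' @return A data.frame of class `wald_table` with an additional `part`
#'   column (`incidence` / `latency`, plus `frailty` for frailty fits).
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "cure_fit"))
  mk <- function(coefs, ses, part) {
    if (is.null(ses)) ses <- rep(NA_real_, length(coefs))
    out <- wald_row(unname(coefs), unname(ses), label = names(coefs))
    out$part <- part
    out
  }
  out <- rbind(mk(fit$incidence$coefficients, fit$incidence$se, "incidence"),
               mk(fit$latency$coefficients, fit$latency$se, "latency"))
  if (!is.null(fit$psi)) {
    fr <- data.frame(label = "psi", coefficient = fit$psi,
                     se = if (is.null(fit$psi_se)) NA_real_ else fit$psi_se,
                     ratio = NA_real_,
                     ci_lower = if (is.null(fit$psi_ci)) NA_real_ else fit$psi_ci[1],
                     ci_upper = if (is.null(fit$psi_ci)) NA_real_ else fit$psi_ci[2],
                     p_value = NA_real_, part = "frailty",
                     stringsAsFactors = FALSE)
    out <- rbind(out, fr)
  }
  if (anyNA(out$se)) attr(out, "note") <- "SEs missing: CIs unavailable; run bootstrap_se()"
  class(out) <- c("wald_table", "data.frame")
  out
}

#' @export
print.wald_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df$p_value <- pmax(df$p_value, 0.001)  # display convention
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "note"))) cat("note:", attr(x, "note"), "\n")
  invisible(x)
}

# Core pair-based concordance on a per-pair risk evaluation.
# risk_fn(t, idx) must return the predicted mortality risk at time t for
# the subjects in idx.
concordance_pairs <- function(time, delta, risk_fn, tie_eps = 1e-12) {
  ev <- which(delta == 1)
  conc <- 0; ties <- 0; total <- 0
  for (i in ev) {
    later <- which(time > time[i])
    if (!length(later)) next
    r <- risk_fn(time[i], c(i, later))
    ri <- r[1]; rj <- r[-1]
    conc <- conc + sum(ri > rj + tie_eps)
    ties <- ties + sum(abs(ri - rj) <= tie_eps)
    total <- total + length(later)
  }
  if (total == 0) stop("no comparable pairs: concordance undefined")
  (conc + 0.5 * ties) / total
}

#' K-index: concordance of a fitted cure model
#'
#' Cure-model concordance over comparable pairs (i, j) with t_i < t_j and
#' delta_i = 1: the proportion of pairs in which subject i's predicted
#' population mortality risk at t_i, 1 - S_pop(t_i | X_i, Z_i), exceeds
#' subject j's risk evaluated at the same time; exact ties count 1/2. The
#' index is invariant to strictly increasing transforms of the risk score
#' and equals 0.5 when the model assigns everyone the same risk.
#'
#' @param fit a `cure_fit`.
#' @param ch the [cohort()] to evaluate on.
#' @return Concordance in `[0, 1]`.
#' @export
k_index <- function(fit, ch) {
  stopifnot(inherits(fit, "cure_fit"), inherits(ch, "cohort"))
  dm <- design_matrices(ch)
  b <- fit$incidence$coefficients
  pi_u <- stats::plogis(incidence_lp(b, dm$Z))
  beta <- fit$latency$coefficients
  ee <- exp(as.vector(dm$X[, names(beta), drop = FALSE] %*% beta))
  psi <- if (is.null(fit$psi)) 0 else fit$psi
  H0 <- function(t) cumhaz_at(fit$latency$baseline, t)
  risk_fn <- function(t, idx) {
    Su <- uncured_survival(H0(t) * ee[idx], psi)
    if (fit$latency$zero_tail && t > fit$max_event_time) Su <- 0 * Su
    pi_u[idx] * (1 - Su)
  }
  concordance_pairs(dm$time, dm$delta, risk_fn)
}

#' Compare fitted cure models by concordance
#'
#' Tabulates the K-index, log-likelihood and parameter count of two or
#' more fits of the same cohort and names the model the K-index prefers
#' (ties are reported as `"tie"`).
#'
#' @param fits named list of `cure_fit` objects fitted to `ch`.
#' @param ch the common [cohort()].
#' @return A list of class `comparison_report`: `table` (data.frame with
#'   `model`, `k_index`, `loglik`, `n_parameters`), `preferred`.
#' @export
compare_models <- function(fits, ch) {
  stopifnot(length(fits) >= 2, inherits(ch, "cohort"))
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$model, character(1))
  }
  n <- n_subjects(ch)
  for (f in fits) {
    if (!inherits(f, "cure_fit")) stop("all elements must be cure_fit objects")
    if (f$n != n) stop("fits were not produced on this cohort (n mismatch)")
  }
  k <- vapply(fits, k_index, numeric(1), ch = ch)
  tab <- data.frame(model = names(fits), k_index = k,
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    n_parameters = vapply(fits, function(f) {
                      length(f$incidence$coefficients) +
                        length(f$latency$coefficients) +
                        as.integer(!is.null(f$psi))
                    }, integer(1)),
                    stringsAsFactors = FALSE)
  best <- which(k == max(k))
  structure(list(table = tab,
                 preferred = if (length(best) > 1) "tie" else tab$model[best]),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("preferred by K-index:", x$preferred, "\n")
  invisible(x)
}

#' Serialize a comparison report to JSON and back
#'
#' @param x a `comparison_report`.
#' @return `report_to_json()`: a JSON string; `report_from_json()`: the
#'   report reconstructed from it.
#' @export
report_to_json <- function(x) {
  stopifnot(inherits(x, "comparison_report"))
  jsonlite::toJSON(list(table = x$table, preferred = x$preferred),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname report_to_json
#' @param json a JSON string produced by `report_to_json()`.
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(table = as.data.frame(obj$table), preferred = obj$preferred),
            class = "comparison_report")
}
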