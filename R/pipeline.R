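#' Serialize a fitted cure model to JSON
#'
#' Coefficients, SEs, baseline step increments, frailty variance (when
#' present), log-likelihood trace and convergence metadata, as a JSON
#' string suitable for archiving a fit alongside its inputs.
#'
#' @param fit a `cure_fit`.
#' @return A JSON string.
#' @export
fit_to_json <- function(fit) {
  stopifnot(inherits(fit, "cure_fit"))
  obj <- list(model = fit$model,
              incidence = list(coefficients = as.list(fit$incidence$coefficients),
                               se = as.list(fit$incidence$se)),
              latency = list(coefficients = as.list(fit$latency$coefficients),
                             se = as.list(fit$latency$se),
                             baseline_time = fit$latency$baseline$time,
                             baseline_hazard = fit$latency$baseline$hazard,
                             zero_tail = fit$latency$zero_tail),
              psi = fit$psi, psi_se = fit$psi_se, psi_ci = fit$psi_ci,
              loglik = fit$loglik, loglik_trace = fit$loglik_trace,
              n_iter = fit$n_iter, converged = fit$converged,
              n = fit$n, n_event = fit$n_event)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full mixture-cure analysis pipeline
#'
#' End-to-end analysis of a cohort: read or simulate -> impute missing
#' covariates -> VIF collinearity check -> Kaplan-Meier, plateau and
#' Maller-Zhou cure test -> fit the semiparametric PH mixture cure model
#' and the mixture cure frailty model -> Wald coefficient tables ->
#' K-index comparison -> per-subject cure probabilities. Any stage failure
#' aborts with the stage name and cause; a cohort with zero events is
#' refused up front. Rerunning with the same seed reproduces every number.
#'
#' @param ch a [cohort()], or `NULL` to simulate one from `config`.
#' @param config a [generator_config()] used when `ch` is `NULL`.
#' @param seed integer seed driving simulation, imputation and bootstrap.
#' @param bootstrap_B bootstrap replicates for the SE stage (default 50;
#'   set 0 to skip SEs).
#' @param m_imputations imputations when covariates are missing (default 5;
#'   the first completed data set is carried forward to modelling).
#' @param out_dir optional directory; when given, cohort, curves, tables,
#'   fits (JSON) and a run log are written there as plain-text files.
#' @return A list of class `cure_pipeline`: `cohort`, `summary`, `vif`,
#'   `km`, `plateau`, `maller_zhou`, `fit_ph`, `fit_frailty`,
#'   `wald_ph`, `wald_frailty`, `comparison`, `cure_probabilities`, `log`.
#' @export
run_pipeline <- function(ch = NULL, config = NULL, seed = 1L,
                         bootstrap_B = 50, m_imputations = 5,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_lines <- c(sprintf("curefrail pipeline, seed = %d, R %s.%s",
                         seed, R.version$major, R.version$minor))

  ch <- stage("input", {
    if (is.null(ch)) {
      if (is.null(config)) stop("supply a cohort or a generator config")
      simulate_cohort(config, seed = seed)$cohort
    } else ch
  })
  if (n_events(ch) == 0) {
    stop("pipeline refused: the cohort contains zero events, so no ",
         "survival model can be fitted")
  }
  log_lines <- c(log_lines, sprintf("cohort: n = %d, events = %d",
                                    n_subjects(ch), n_events(ch)))

  ch <- stage("imputation", {
    if (anyNA(ch$data[, covariate_names(ch), drop = FALSE])) {
      impute_missing(ch, m = m_imputations, seed = seed)[[1]]
    } else ch
  })
  vif <- stage("vif", compute_vif(ch))
  summ <- stage("summary", summarize_cohort(ch))
  km <- stage("kaplan_meier", kaplan_meier(ch))
  plat <- stage("plateau", plateau_length(km))
  mz <- stage("maller_zhou", maller_zhou_test(ch))
  se_mode <- if (bootstrap_B >= 2) "bootstrap" else "none"
  fit_ph <- stage("fit_cure_ph",
                  fit_mixture_cure_ph(ch, se = se_mode, B = bootstrap_B,
                                      seed = seed))
  fit_fr <- stage("fit_cure_frailty",
                  fit_mixture_cure_frailty(ch, se = se_mode, B = bootstrap_B,
                                           seed = seed))
  wald_ph <- stage("wald_tables", wald_table(fit_ph))
  wald_fr <- stage("wald_tables", wald_table(fit_fr))
  comp <- stage("comparison",
                compare_models(list(cure_ph = fit_ph, cure_frailty = fit_fr),
                               ch))
  curep <- stage("cure_probabilities",
                 cure_probability(fit_fr, ch$data[, covariate_names(ch),
                                                  drop = FALSE]))
  log_lines <- c(log_lines,
                 sprintf("maller-zhou: cure fraction %.4f, p = %.4g",
                         mz$estimated_cure_fraction, mz$p_value),
                 sprintf("k-index: ph %.4f, frailty %.4f; preferred %s",
                         comp$table$k_index[1], comp$table$k_index[2],
                         comp$preferred))

  out <- structure(list(cohort = ch, summary = summ, vif = vif, km = km,
                        plateau = plat, maller_zhou = mz,
                        fit_ph = fit_ph, fit_frailty = fit_fr,
                        wald_ph = wald_ph, wald_frailty = wald_fr,
                        comparison = comp, cure_probabilities = curep,
                        log = log_lines),
                   class = "cure_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(ch, file.path(out_dir, "cohort.csv"))
    utils::write.csv(as.data.frame(km), file.path(out_dir, "km_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(summ), file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(wald_ph),
                     file.path(out_dir, "wald_cure_ph.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(wald_fr),
                     file.path(out_dir, "wald_cure_frailty.csv"),
                     row.names = FALSE)
    writeLines(fit_to_json(fit_ph), file.path(out_dir, "fit_cure_ph.json"))
    writeLines(fit_to_json(fit_fr), file.path(out_dir, "fit_cure_frailty.json"))
    writeLines(report_to_json(comp), file.path(out_dir, "comparison.json"))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.cure_pipeline <- function(x, ...) {
  writeLines(x$log)
  invisible(x)
}

#' Read and write generator configurations as YAML
#'
#' @param config a [generator_config()].
#' @param path file path.
#' @return `write_generator_config()`: `path` invisibly;
#'   `read_generator_config()`: a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path,
    precision = 17)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  obj <- yaml::read_yaml(path)
  generator_config(n = obj$n,
                   prevalences = unlist(obj$prevalences),
                   theta = unlist(obj$theta),
                   beta = unlist(obj$beta),
                   baseline = obj$baseline,
                   psi = obj$psi,
                   censoring = obj$censoring,
                   seed = obj$seed)
}
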