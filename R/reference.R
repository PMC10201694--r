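#' Published reference values from the motivating HIV cohort
#'
#' The package ships the printed summary statistics of the motivating study
#' (a registry of 2170 HIV-infected individuals, Kermanshah Province,
#' 1998--2019) as plain-text fixtures: the baseline descriptive counts per
#' covariate level (overall and among deaths) and the fitted coefficient
#' tables of the semiparametric PH mixture cure model and the mixture cure
#' frailty model. They seed [default_hiv_config()] and serve as the
#' reference against which the Wald-table transforms are checked. The raw
#' subject-level registry itself is not public and is not included.
#'
#' @return `hiv_reference_counts()`: data.frame with `variable`, `level`,
#'   `coded_value`, `n_total`, `n_dead`.
#' @export
hiv_reference_counts <- function() {
  utils::read.csv(system.file("extdata", "hiv_reference_counts.csv",
                              package = "curefrail"),
                  stringsAsFactors = FALSE)
}

#' @rdname hiv_reference_counts
#' @return `hiv_reference_estimates()`: data.frame with `part`
#'   (incidence/latency/frailty), `model` (ph/frailty), `variable`, `label`,
#'   `coefficient`, `se`, the published ratio (OR or HR) and 95% CI, and an
#'   erratum flag marking the one printed ratio that is inconsistent with
#'   its own coefficient and CI.
#' @export
hiv_reference_estimates <- function() {
  utils::read.csv(system.file("extdata", "hiv_reference_estimates.csv",
                              package = "curefrail"),
                  stringsAsFactors = FALSE)
}

#' Marginal covariate prevalences of the reference cohort
#'
#' Proportion coded 1 for each covariate, computed from the published
#' level counts.
#'
#' @return Named numeric vector of prevalences in (0, 1).
#' @export
hiv_reference_prevalences <- function() {
  cnt <- hiv_reference_counts()
  pos <- cnt[cnt$coded_value == 1, ]
  tot <- tapply(cnt$n_total, cnt$variable, sum)
  p <- pos$n_total / as.numeric(tot[pos$variable])
  names(p) <- pos$variable
  p
}
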