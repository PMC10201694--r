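#' Covariate schema for a survival cohort
#'
#' A schema declares the binary covariates a cohort may carry, the label of
#' each and which level is coded 1 (with the reference level coded 0). It is
#' the contract against which [read_cohort()] validates input tables, and it
#' carries the default incidence (`Z`) and latency (`X`) covariate lists used
#' by the model-fitting functions.
#'
#' @param covariates character vector of covariate column names.
#' @param labels display labels, e.g. `"Imprisonment (Yes / No)"`; recycled
#'   from `covariates` when omitted.
#' @param positive_levels name of the level coded 1, per covariate.
#' @param reference_levels name of the level coded 0, per covariate.
#' @param incidence covariates entering the logistic incidence part
#'   (default: all).
#' @param latency covariates entering the PH latency part (default: all).
#' @return An object of class `cure_schema`.
#' @seealso [default_hiv_schema()]
#' @export
cure_schema <- function(covariates,
                        labels = covariates,
                        positive_levels = rep("1", length(covariates)),
                        reference_levels = rep("0", length(covariates)),
                        incidence = covariates,
                        latency = covariates) {
  stopifnot(is.character(covariates), length(covariates) >= 1,
            !anyDuplicated(covariates))
  if (!all(incidence %in% covariates) || !all(latency %in% covariates)) {
    stop("incidence/latency covariates must be declared in the schema")
  }
  structure(list(
    table = data.frame(name = covariates,
                       label = rep_len(labels, length(covariates)),
                       positive_level = rep_len(positive_levels, length(covariates)),
                       reference_level = rep_len(reference_levels, length(covariates)),
                       stringsAsFactors = FALSE),
    incidence = incidence,
    latency = latency
  ), class = "cure_schema")
}

#' Schema of the reference HIV cohort
#'
#' Ten binary covariates coded as in the motivating registry of 2170
#' HIV-infected individuals (Kermanshah Province, 1998--2019): the level
#' named first in each label is coded 1, its reference 0 (e.g. age > 33
#' coded 1, male coded 1, ART received coded 1). The same ten covariates
#' enter both the incidence and the latency model part by default.
#'
#' @return A `cure_schema` with covariates `age_gt33`, `gender_male`,
#'   `married`, `art`, `tb`, `high_education`, `imprisonment`, `drug_abuse`,
#'   `employed`, `idu_transmission`.
#' @export
default_hiv_schema <- function() {
  est <- hiv_reference_estimates()
  inc <- est[est$part == "incidence" & est$model == "frailty" &
               est$variable != "intercept", , drop = FALSE]
  cure_schema(covariates = inc$variable, labels = inc$label,
              positive_levels = sub("^.*\\(([^/]+) */.*$", "\\1", inc$label),
              reference_levels = sub("^.*/ *([^)]+)\\).*$", "\\1", inc$label))
}

#' Construct a cohort from subject-level survival data
#'
#' @param data a data.frame with columns `subject_id`, `time` (months,
#'   nonnegative), `event` (1 = death, 0 = censored) and one 0/1 column per
#'   schema covariate (NA allowed for missing covariate values).
#' @param schema a [cure_schema()]; defaults to a schema built from the
#'   covariate columns found in `data`.
#' @return An object of class `cohort`: the validated data plus the schema.
#' @export
cohort <- function(data, schema = NULL) {
  stopifnot(is.data.frame(data))
  req <- c("time", "event")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(data$subject_id)) data$subject_id <- seq_len(nrow(data))
  if (is.null(schema)) {
    covs <- setdiff(names(data), c("subject_id", "time", "event"))
    if (!length(covs)) stop("cohort has no covariate columns and no schema")
    schema <- cure_schema(covs)
  }
  stopifnot(inherits(schema, "cure_schema"))
  covs <- schema$table$name
  miss <- setdiff(covs, names(data))
  if (length(miss)) stop("schema covariate(s) absent from data: ",
                         paste(miss, collapse = ", "))
  data <- data[, c("subject_id", "time", "event", covs), drop = FALSE]
  if (nrow(data) < 1) stop("cohort must contain at least one subject")

  bad <- which(!is.finite(data$time) | !is.finite(data$event))
  if (length(bad)) stop("unparseable or missing time/event in row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(data$time < 0)
  if (length(bad)) stop("negative follow-up time in row(s): ",
                        paste(bad, collapse = ", "))
  if (!all(data$event %in% c(0, 1))) {
    bad <- which(!data$event %in% c(0, 1))
    stop("event must be 0/1; offending row(s): ", paste(bad, collapse = ", "))
  }
  for (cv in covs) {
    v <- data[[cv]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop("covariate '", cv, "' must be 0/1 or NA")
    }
  }
  structure(list(data = data, schema = schema), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("Cohort: %d subjects, %d deaths (%.1f%% censored), %d covariates\n",
              nrow(d), sum(d$event), 100 * mean(d$event == 0),
              length(x$schema$table$name)))
  invisible(x)
}

n_subjects <- function(ch) nrow(ch$data)
n_events <- function(ch) sum(ch$data$event)
covariate_names <- function(ch) ch$schema$table$name

#' Read a cohort from a delimited file
#'
#' Reads a CSV with columns `subject_id`, `time`, `event` and the schema's
#' covariate columns. Rows whose time or event fails to parse as a number
#' are rejected with a warning naming the row numbers; negative times and
#' non-0/1 events are validation errors naming the offending rows.
#'
#' @param path path to a CSV file with a header row.
#' @param schema a [cure_schema()]; `NULL` derives one from the columns.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time", "event")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("missing required column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  tnum <- suppressWarnings(as.numeric(raw$time))
  enum <- suppressWarnings(as.numeric(raw$event))
  bad <- which((is.na(tnum) & !is.na(raw$time) & raw$time != "") |
                 (is.na(enum) & !is.na(raw$event) & raw$event != "") |
                 is.na(raw$time) | is.na(raw$event))
  if (length(bad)) {
    warning("rejecting ", length(bad), " row(s) with unparseable time/event: ",
            paste(utils::head(bad, 20), collapse = ", "))
    raw <- raw[-bad, , drop = FALSE]
    tnum <- tnum[-bad]; enum <- enum[-bad]
  }
  raw$time <- tnum
  raw$event <- enum
  covs <- if (is.null(schema)) {
    setdiff(names(raw), c("subject_id", "time", "event"))
  } else schema$table$name
  for (cv in intersect(covs, names(raw))) {
    raw[[cv]] <- suppressWarnings(as.numeric(raw[[cv]]))
  }
  cohort(raw, schema)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(ch, f))` returns a
#' cohort with identical values.
#'
#' @param ch a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ch, path) {
  stopifnot(inherits(ch, "cohort"))
  utils::write.csv(ch$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Multiple imputation of missing binary covariates
#'
#' Fills missing covariate cells by the multiple-regression method: each
#' incomplete binary covariate is regressed (logistic link) on all fully
#' observed covariates plus follow-up time and the event indicator; missing
#' cells are completed by Bernoulli draws from the fitted probabilities.
#' Observed cells are never altered, and time/event must be complete (the
#' cohort constructor enforces this). Repeating the call with the same seed
#' reproduces the imputed tables exactly.
#'
#' @param ch a [cohort()].
#' @param m number of imputed data sets (default 5).
#' @param seed integer seed driving the Bernoulli draws.
#' @return A list of `m` completed cohorts. If the cohort has no missing
#'   values, `m` copies of the input.
#' @export
impute_missing <- function(ch, m = 5, seed = 1) {
  stopifnot(inherits(ch, "cohort"), m >= 1)
  d <- ch$data
  covs <- covariate_names(ch)
  n_miss <- vapply(d[covs], function(v) sum(is.na(v)), integer(1))
  if (any(n_miss == nrow(d))) {
    stop("covariate(s) missing for all subjects cannot be imputed: ",
         paste(covs[n_miss == nrow(d)], collapse = ", "))
  }
  if (all(n_miss == 0)) return(replicate(m, ch, simplify = FALSE))

  complete_covs <- covs[n_miss == 0]
  incomplete <- covs[n_miss > 0]
  base <- cbind(d[, c("time", "event"), drop = FALSE],
                d[, complete_covs, drop = FALSE])
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(m), function(k) {
    dk <- d
    for (cv in incomplete) {
      obs <- !is.na(d[[cv]])
      fit <- suppressWarnings(stats::glm(d[[cv]][obs] ~ .,
                                         data = base[obs, , drop = FALSE],
                                         family = stats::binomial()))
      p <- stats::predict(fit, newdata = base[!obs, , drop = FALSE],
                          type = "response")
      dk[[cv]][!obs] <- stats::rbinom(sum(!obs), 1, p)
    }
    cohort(dk, ch$schema)
  })
}

#' Variance inflation factors for cohort covariates
#'
#' For each requested covariate j, regresses it linearly on all the others
#' and reports VIF_j = 1 / (1 - R^2_j). Exact collinearity (R^2 = 1) is
#' flagged with an infinite VIF rather than raising an error.
#'
#' @param ch a [cohort()] with complete covariates.
#' @param covariates covariate names to check (default: all in the schema).
#' @return A data.frame with columns `covariate`, `vif`,
#'   `exact_collinear`, of class `vif_table`.
#' @export
compute_vif <- function(ch, covariates = covariate_names(ch)) {
  stopifnot(inherits(ch, "cohort"), length(covariates) >= 2)
  d <- ch$data[, covariates, drop = FALSE]
  if (anyNA(d)) stop("covariates must be complete; impute first")
  out <- data.frame(covariate = covariates, vif = NA_real_,
                    exact_collinear = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(covariates)) {
    y <- d[[i]]
    Xo <- as.matrix(d[, -i, drop = FALSE])
    if (stats::var(y) == 0) next  # degenerate column: VIF undefined
    fit <- stats::lm.fit(cbind(1, Xo), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 > 1 - 1e-12) {
      out$vif[i] <- Inf
      out$exact_collinear[i] <- TRUE
    } else {
      out$vif[i] <- 1 / (1 - r2)
    }
  }
  class(out) <- c("vif_table", "data.frame")
  out
}

#' Descriptive summary of a cohort
#'
#' Per covariate level: count and percent in the whole cohort and among
#' subjects who died, in the style of a baseline-characteristics table. The
#' overall censoring proportion is attached as an attribute and printed.
#'
#' @param ch a [cohort()].
#' @return A data.frame of class `cohort_summary` with columns `variable`,
#'   `level`, `n_total`, `pct_total`, `n_dead`, `pct_dead`; attribute
#'   `censored_pct` holds the overall censoring percentage.
#' @export
summarize_cohort <- function(ch) {
  stopifnot(inherits(ch, "cohort"))
  d <- ch$data
  sch <- ch$schema$table
  ndead <- sum(d$event == 1)
  rows <- lapply(seq_len(nrow(sch)), function(i) {
    cv <- sch$name[i]
    lev <- c(sch$reference_level[i], sch$positive_level[i])
    out <- lapply(0:1, function(val) {
      sel <- !is.na(d[[cv]]) & d[[cv]] == val
      data.frame(variable = cv, level = lev[val + 1],
                 n_total = sum(sel),
                 pct_total = 100 * sum(sel) / sum(!is.na(d[[cv]])),
                 n_dead = sum(sel & d$event == 1),
                 pct_dead = if (ndead > 0)
                   100 * sum(sel & d$event == 1) / sum(d$event == 1 & !is.na(d[[cv]]))
                 else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  attr(out, "censored_pct") <- 100 * mean(d$event == 0)
  attr(out, "n") <- nrow(d)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Cohort summary (n = %d, %.1f%% censored)\n",
              attr(x, "n"), attr(x, "censored_pct")))
  df <- as.data.frame(x)
  df$pct_total <- round(df$pct_total, digits)
  df$pct_dead <- round(df$pct_dead, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
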