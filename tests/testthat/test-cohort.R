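test_that("read_cohort parses a valid table and validates bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,time,event,x", "1,1,1,0", "2,2,0,1", "3,3,1,0"), f)
  ch <- read_cohort(f)
  expect_equal(n_subjects <- nrow(ch$data), 3)
  expect_equal(sum(ch$data$event), 2)

  writeLines(c("subject_id,time,event,x", "1,1,1,0", "2,-1,0,1"), f)
  expect_error(read_cohort(f), "negative follow-up time.*2")

  writeLines(c("subject_id,event,x", "1,1,0"), f)
  expect_error(read_cohort(f), "missing required column")

  writeLines(c("subject_id,time,event,x", "1,1,1,0", "2,oops,0,1", "3,3,1,0"), f)
  expect_warning(ch <- read_cohort(f), "unparseable")
  expect_equal(nrow(ch$data), 2)
})

test_that("write/read round-trip is the identity on a simulated cohort", {
  sim <- simulate_cohort(default_hiv_config(), seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, f)
  back <- read_cohort(f, schema = sim$cohort$schema)
  expect_equal(back$data, sim$cohort$data, tolerance = 1e-12)
})

test_that("imputation is a seeded no-op on complete data and only fills gaps", {
  sim <- simulate_cohort(default_hiv_config(n = 400), seed = 3)
  imps <- impute_missing(sim$cohort, m = 3, seed = 5)
  expect_length(imps, 3)
  for (im in imps) expect_identical(im$data, sim$cohort$data)

  d <- sim$cohort$data
  miss <- seq(1, nrow(d), by = 5)
  d$art[miss] <- NA
  chm <- cohort(d, sim$cohort$schema)
  a <- impute_missing(chm, m = 2, seed = 9)
  b <- impute_missing(chm, m = 2, seed = 9)
  expect_identical(a[[1]]$data, b[[1]]$data)
  expect_identical(a[[2]]$data, b[[2]]$data)
  expect_false(identical(a[[1]]$data$art, a[[2]]$data$art))
  # observed cells untouched, missing cells filled
  expect_identical(a[[1]]$data$art[-miss], sim$cohort$data$art[-miss])
  expect_false(anyNA(a[[1]]$data$art))

  d$tb <- NA
  expect_error(impute_missing(cohort(d, sim$cohort$schema)),
               "missing for all subjects")
})

test_that("MCAR imputation recovers complete-data association estimates", {
  sim <- simulate_cohort(default_hiv_config(n = 1500), seed = 21)
  d <- sim$cohort$data
  covs <- names(sim$cohort$schema$table$name)
  full_fit <- glm(event ~ art + tb + imprisonment, data = d,
                  family = binomial)
  set.seed(77)
  d$art[rbinom(nrow(d), 1, 0.2) == 1] <- NA
  imps <- impute_missing(cohort(d, sim$cohort$schema), m = 5, seed = 31)
  coefs <- sapply(imps, function(ch) {
    coef(glm(event ~ art + tb + imprisonment, data = ch$data,
             family = binomial))
  })
  pooled <- rowMeans(coefs)
  se_full <- summary(full_fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(pooled - coef(full_fit)) < 2 * se_full))
})

test_that("VIF matches an independent regression oracle and flags collinearity", {
  # exactly orthogonal balanced design: VIF = 1 to numerical tolerance
  d <- expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1)
  d <- d[rep(seq_len(nrow(d)), 5), ]
  d$subject_id <- seq_len(nrow(d)); d$time <- 1; d$event <- rep_len(0:1, nrow(d))
  v <- compute_vif(cohort(d))
  expect_true(all(abs(v$vif - 1) < 1e-10))

  # duplicate column: exact collinearity flagged, not an error
  d$x4 <- d$x1
  v <- compute_vif(cohort(d))
  expect_true(v$exact_collinear[v$covariate == "x4"])
  expect_true(is.infinite(v$vif[v$covariate == "x1"]))

  # correlated covariates: VIF = 1 / (1 - R^2) from an independent lm fit
  set.seed(4)
  n <- 800
  x1 <- rbinom(n, 1, 0.5)
  x2 <- ifelse(runif(n) < 0.9, x1, 1 - x1)  # strongly associated with x1
  x3 <- rbinom(n, 1, 0.4)
  dc <- data.frame(subject_id = 1:n, time = 1, event = rep_len(0:1, n),
                   x1 = x1, x2 = x2, x3 = x3)
  v <- compute_vif(cohort(dc))
  oracle <- 1 / (1 - summary(lm(x1 ~ x2 + x3))$r.squared)
  expect_equal(v$vif[v$covariate == "x1"], oracle, tolerance = 1e-10)
  expect_true(all(v$vif >= 1))
})

test_that("cohort summary reproduces generator prevalences and sums to 100%", {
  sim <- simulate_cohort(default_hiv_config(n = 2170), seed = 13)
  s <- summarize_cohort(sim$cohort)
  prev <- hiv_reference_prevalences()
  pos <- s[s$level != "" & !is.na(s$pct_total), ]
  for (v in names(prev)) {
    rows <- s[s$variable == v, ]
    expect_equal(sum(rows$pct_total), 100, tolerance = 1e-9)
    p_hat <- rows$pct_total[2] / 100  # coded-1 level listed second
    se <- sqrt(prev[[v]] * (1 - prev[[v]]) / 2170)
    expect_lt(abs(p_hat - prev[[v]]), 4 * se)
  }
  expect_equal(attr(s, "censored_pct"),
               100 * mean(sim$cohort$data$event == 0))

  one <- cohort(data.frame(subject_id = 1, time = 5, event = 1, x = 1))
  s1 <- summarize_cohort(one)
  expect_equal(s1$pct_total[s1$level == "1"], 100)
  expect_equal(s1$pct_dead[s1$level == "1"], 100)
})
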