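origin <- as.Date("2016-01-01")

# minimal registry world with one episode per patient, controlled ratings
mk_world <- function(rating_offsets, scores = 20) {
  n <- length(rating_offsets)
  status <- data.frame(patient_id = seq_len(n), episode_id = seq_len(n),
                       episode_number = 1L, start_date = origin,
                       end_date = origin + 400,
                       care_setting_at_start = "nonpsychiatric",
                       is_trd = FALSE, index_date = as.Date(NA),
                       time_to_trd_days = NA_real_, n_trials = 1L)
  tables <- list(
    demographics = data.frame(patient_id = seq_len(n),
                              birth_date = origin - 40 * 365,
                              sex = "F", ses = 1L,
                              residency_start = as.Date("2010-01-01"),
                              residency_end = as.Date("2018-12-31")),
    vital_status = data.frame(patient_id = seq_len(n),
                              death_date = as.Date(NA)),
    diagnoses = data.frame(patient_id = integer(0),
                           date = as.Date(character(0)), icd10 = character(0),
                           care_setting = character(0), locus = character(0),
                           discharge_date = as.Date(character(0))),
    dispensations = data.frame(patient_id = integer(0),
                               date = as.Date(character(0)),
                               atc = character(0), supply_days = integer(0),
                               daily_dose_mg = numeric(0)),
    ratings = data.frame(patient_id = seq_len(n),
                         date = origin - rating_offsets,
                         score = rep_len(scores, n)))
  list(status = status, tables = tables)
}

test_that("the MADRS-S window is 1-14 days strictly before episode start", {
  w <- mk_world(c(15, 14, 1, 0))
  ft <- build_features(w$status, w$tables)
  expect_equal(is.na(ft$madrs), c(TRUE, FALSE, FALSE, TRUE))
  # same-day duplicate ratings resolve to the maximum score
  w2 <- mk_world(c(5, 5), scores = c(10, 30))
  w2$tables$ratings$patient_id <- c(1L, 1L)
  w2$status <- w2$status[1, ]
  ft2 <- build_features(w2$status, w2$tables)
  expect_equal(ft2$madrs, 30)
})

test_that("the outcome is TRD within one year, administratively censored", {
  w <- mk_world(c(5, 5, 5))
  w$status$is_trd <- c(TRUE, TRUE, FALSE)
  w$status$index_date <- origin + c(200, 400, NA)
  w$status$time_to_trd_days <- c(200, 400, NA)
  ft <- build_features(w$status, w$tables)
  expect_equal(ft$event, c(TRUE, FALSE, FALSE))
  expect_equal(ft$time, c(200, 365, 365))
})

test_that("residency and start-window eligibility bound the secondary sample", {
  w <- mk_world(c(5, 5))
  w$tables$demographics$residency_start[2] <- origin - 2 * 365  # 2 years only
  ft <- build_features(w$status, w$tables)
  expect_equal(ft$patient_id, 1L)
  w3 <- mk_world(5)
  w3$status$start_date <- as.Date("2014-06-01")   # before the window
  w3$status$end_date <- w3$status$start_date + 400
  expect_equal(nrow(build_features(w3$status, w3$tables)), 0L)
})

test_that("imputation is an identity on complete data and deterministic under seed", {
  set.seed(2)
  ft <- data.table::data.table(madrs = rnorm(50, 20, 5), x = rnorm(50),
                               event = runif(50) < 0.3,
                               time = sample(30:365, 50, TRUE))
  data.table::setattr(ft, "covariates", c("madrs", "x"))
  imp <- impute_missing(ft, m = 3, seed = 1)
  expect_length(imp, 3L)
  for (d in imp) expect_equal(as.data.frame(d), as.data.frame(ft))

  ft2 <- data.table::copy(ft)
  ft2$madrs[1:30] <- NA
  i1 <- impute_missing(ft2, m = 2, seed = 5)
  i2 <- impute_missing(ft2, m = 2, seed = 5)
  expect_identical(lapply(i1, as.data.frame), lapply(i2, as.data.frame))
  i3 <- impute_missing(ft2, m = 2, seed = 6)
  expect_false(identical(lapply(i1, as.data.frame),
                         lapply(i3, as.data.frame)))
  expect_true(all(!is.na(i1[[1]]$madrs)))
  expect_true(all(i1[[1]]$madrs >= 0 & i1[[1]]$madrs <= 54))

  ft3 <- data.table::copy(ft)
  ft3$madrs <- NA_real_
  expect_error(impute_missing(ft3, m = 2, seed = 1), "fully missing")
})

test_that("Rubin pooling identities hold exactly", {
  set.seed(11)
  m <- 7; p <- 3
  coefs <- matrix(rnorm(m * p), m, p, dimnames = list(NULL, letters[1:p]))
  vcovs <- lapply(seq_len(m), function(i) {
    A <- matrix(rnorm(p * p), p); crossprod(A) })
  pl <- pool_rubin(coefs, vcovs)
  expect_equal(pl$coefficients, colMeans(coefs))
  expect_equal(pl$vcov, pl$within + (1 + 1 / m) * pl$between,
               ignore_attr = TRUE)
  expect_equal(unname(pl$between), unname(stats::cov(coefs)))
})

test_that("pooling m identical tables equals the single-table fit", {
  set.seed(3)
  n <- 400
  d <- data.table::data.table(x = rnorm(n), z = runif(n) < 0.5)
  lp <- 0.7 * d$x
  d$time <- rexp(n, 0.002 * exp(lp))
  d$event <- d$time < 365
  d$time <- pmin(d$time, 365)
  single <- survival::coxph(survival::Surv(time, event) ~ x + z, data = d)
  tabs <- lapply(1:4, function(i) d)
  pooled <- fit_full_model(tabs, covariates = c("x", "z"))
  expect_equal(pooled$coefficients, stats::coef(single), tolerance = 1e-10)
  expect_equal(max(abs(pooled$between)), 0, tolerance = 1e-12)
  expect_equal(pooled$vcov, stats::vcov(single), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("a binary covariate doubling the hazard is recovered near log 2", {
  set.seed(19)
  n <- 4000
  d <- data.table::data.table(z = rep(c(0, 1), n / 2), x = rnorm(n))
  d$time <- rexp(n, 0.003 * exp(log(2) * d$z))
  d$event <- d$time < 365
  d$time <- pmin(d$time, 365)
  fit <- fit_full_model(d, covariates = c("z", "x"))
  se <- sqrt(diag(fit$vcov))["z"]
  expect_lt(abs(fit$coefficients["z"] - log(2)), 2.5 * se)
  # an all-censored outcome is inestimable
  d0 <- data.table::copy(d)
  d0$event <- FALSE
  expect_error(fit_full_model(d0, covariates = c("z", "x")))
})

test_that("model reduction respects the threshold and its limits", {
  set.seed(23)
  n <- 1500
  d <- data.table::data.table(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                              noise1 = rnorm(n), noise2 = rnorm(n))
  lp <- 1.5 * d$a + 0.02 * d$noise1
  d$time <- rexp(n, 0.004 * exp(lp))
  d$event <- d$time < 365
  d$time <- pmin(d$time, 365)
  full <- fit_full_model(d, covariates = c("a", "b", "c", "noise1", "noise2"))
  # threshold 1 returns the full variable set with fraction 1
  r1 <- reduce_model(full, d, threshold = 1)
  expect_setequal(r1$variables, full$covariates)
  expect_equal(r1$achieved, 1, tolerance = 1e-9)
  # one dominant covariate: a single-variable model reaches 0.95
  r2 <- reduce_model(full, d, threshold = 0.95)
  expect_true("a" %in% r2$variables)
  expect_lt(length(r2$variables), length(full$covariates))
  expect_gte(r2$achieved, 0.95)
  expect_error(reduce_model(full, d, threshold = 0), "threshold")
  expect_error(reduce_model(full, d, threshold = 1.2), "threshold")
})

test_that("the concordance index matches the all-pairs oracle", {
  set.seed(41)
  for (k in 1:10) {
    n <- sample(30:200, 1)
    time <- round(rexp(n, 0.01), 3)
    event <- runif(n) < 0.6
    score <- rnorm(n)
    expect_equal(concordance_index(time, event, score),
                 oracle_concordance(time, event, score),
                 tolerance = 1e-12)
  }
})

test_that("validation is seeded and flags bad inputs", {
  set.seed(29)
  n <- 500
  d <- data.table::data.table(a = rnorm(n), b = rnorm(n))
  d$time <- rexp(n, 0.004 * exp(d$a))
  d$event <- d$time < 365
  d$time <- pmin(d$time, 365)
  full <- fit_full_model(d, covariates = c("a", "b"))
  red <- reduce_model(full, d, threshold = 0.9)
  v1 <- validate_model(red, d, n_boot = 10, seed = 3)
  v2 <- validate_model(red, d, n_boot = 10, seed = 3)
  expect_identical(v1$optimism, v2$optimism)
  expect_true(v1$c_apparent > 0.5)
  expect_error(validate_model(red, d, n_boot = 1), "n_boot")
})

test_that("the nomogram normalises points and yields a monotone risk lookup", {
  set.seed(31)
  n <- 800
  d <- data.table::data.table(z = rep(c(0, 1), n / 2), x = rnorm(n))
  d$time <- rexp(n, 0.004 * exp(0.9 * d$z + 0.1 * d$x))
  d$event <- d$time < 365
  d$time <- pmin(d$time, 365)
  full <- fit_full_model(d, covariates = c("z", "x"))
  red <- reduce_model(full, d, threshold = 1)
  nm <- export_nomogram(red, d)
  spans <- tapply(nm$points$points, nm$points$variable, max)
  expect_equal(max(spans), 100)
  expect_false(is.unsorted(nm$risk_lookup$risk))
  expect_true(all(nm$risk_lookup$risk >= 0 & nm$risk_lookup$risk <= 1))
  # doubling a coefficient doubles its point span before renormalisation
  red2 <- red
  red2$coefficients["x"] <- 2 * red$coefficients["x"]
  nm2 <- export_nomogram(red2, d)
  ratio0 <- max(nm$points$points[nm$points$variable == "x"]) /
    max(nm$points$points[nm$points$variable == "z"])
  ratio2 <- max(nm2$points$points[nm2$points$variable == "x"]) /
    max(nm2$points$points[nm2$points$variable == "z"])
  expect_equal(ratio2, 2 * ratio0, tolerance = 1e-9)
  # a model with one binary covariate spans exactly 0-100
  red_z <- reduce_model(full, d, threshold = 0.5)
  if (length(red_z$variables) == 1L) {
    nmz <- export_nomogram(red_z, d)
    expect_equal(sort(unique(nmz$points$points)), c(0, 100))
  }
})

test_that("the fitted risk model object behaves like a model", {
  co <- simulate_cohort(sim_config(n_patients = 2500, seed = 13))
  cl <- run_classification(co$tables)
  ft <- build_features(cl$status, co$tables)
  rmod <- trd_risk_model(ft, m = 3, n_boot = 10, seed = 4)
  expect_s3_class(rmod, "trd_risk_model")
  expect_true(is.numeric(coef(rmod)))
  lp <- predict(rmod, type = "lp")
  rk <- predict(rmod, type = "risk")
  expect_length(lp, nrow(ft))
  expect_true(all(rk >= 0 & rk <= 1))
  expect_equal(order(lp), order(rk))   # risk is monotone in the score
  expect_output(print(rmod), "TRD prognostic risk model")
  expect_gte(rmod$reduced$achieved, rmod$threshold - 1e-9)
})
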