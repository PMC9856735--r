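#' Build the prognostic feature table
#'
#' One row per eligible MDD episode of the secondary sample: episodes
#' starting in the final study years whose patient had at least
#' `residency_years` of pre-start residency. Features follow the candidate
#' set of the risk score: MADRS-S from the latest structured rating 1-14
#' days before episode start (otherwise missing), care type at episode
#' start, outpatient visit count in the 12 months before start, sleep
#' disorder diagnosis or sedative fill in the prior 3 years, anxiety
#' diagnosis or anxiolytic fill in the prior 3 years, sex, plus age, prior
#' episode count and a substance-use flag. The outcome is TRD within
#' `horizon_days` of episode start, censored at emigration, death or the end
#' of the study.
#'
#' @param status classified episode table (post-exclusion).
#' @param tables registry tables.
#' @param window_start,window_end episode-start window of the secondary
#'   sample.
#' @param residency_years required pre-start residency.
#' @param madrs_window_days length of the pre-start MADRS-S window.
#' @param horizon_days prediction horizon (administrative censoring).
#' @param study_end end of follow-up.
#' @return data.table feature table with `event` and `time` columns.
#' @export
build_features <- function(status, tables,
                           window_start = "2015-01-01",
                           window_end = "2017-12-31",
                           residency_years = 3, madrs_window_days = 14L,
                           horizon_days = 365L, study_end = "2018-12-31") {
  st <- data.table::as.data.table(status)
  dem <- data.table::as.data.table(tables$demographics)
  st <- st[start_date >= as_day(window_start) & start_date <= as_day(window_end)]
  st[dem, on = "patient_id",
     `:=`(sex = i.sex, birth_date = i.birth_date,
          res_start = i.residency_start, res_end = i.residency_end)]
  st <- st[as.numeric(start_date - res_start) >= residency_years * 365.25]
  if (!nrow(st)) return(st)

  rt <- data.table::as.data.table(tables$ratings)
  # latest rating 1..madrs_window_days days before start; same-day ties: max
  rr <- rt[st[, .(episode_id, patient_id, w0 = start_date - madrs_window_days,
                  w1 = start_date - 1L)],
           on = .(patient_id, date >= w0, date <= w1),
           .(episode_id = i.episode_id, date = x.date, score),
           nomatch = NULL]
  if (nrow(rr)) {
    rr <- rr[order(episode_id, -as.integer(date), -score)]
    rr <- rr[!duplicated(episode_id)]
    st[rr, on = "episode_id", madrs := i.score]
  }
  if (!"madrs" %in% names(st)) st[, madrs := NA_real_]

  dx <- data.table::as.data.table(tables$diagnoses)
  rx <- data.table::as.data.table(tables$dispensations)
  lookup_flag <- function(dx_prefixes, atc_prefixes, days) {
    hits <- list()
    if (!is.null(dx_prefixes) && nrow(dx)) {
      hits$dx <- dx[code_matches(icd10, dx_prefixes), .(patient_id, date)]
    }
    if (!is.null(atc_prefixes) && nrow(rx)) {
      hits$rx <- rx[code_matches(atc, atc_prefixes), .(patient_id, date)]
    }
    hits <- data.table::rbindlist(hits)
    if (!nrow(hits)) return(rep(FALSE, nrow(st)))
    h <- hits[st[, .(episode_id, patient_id, w0 = start_date - days,
                     w1 = start_date - 1L)],
              on = .(patient_id, date >= w0, date <= w1),
              .(episode_id = i.episode_id, date = x.date), nomatch = NULL]
    st$episode_id %in% h$episode_id
  }
  st[, sleep_3y := lookup_flag(c("G47", "F51"), "N05C", 1095L)]
  st[, anxiety_3y := lookup_flag("F41", "N05B", 1095L)]
  st[, substance_3y := lookup_flag(paste0("F1", 0:9), NULL, 1095L)]
  vis <- dx[locus == "outpatient",
            .(patient_id, date)][st[, .(episode_id, patient_id,
                                        w0 = start_date - 365L,
                                        w1 = start_date - 1L)],
                                 on = .(patient_id, date >= w0, date <= w1),
                                 .(episode_id = i.episode_id), nomatch = NULL]
  nv <- vis[, .N, by = episode_id]
  st[, visits_12m := 0L]
  if (nrow(nv)) st[nv, on = "episode_id", visits_12m := i.N]

  vt <- data.table::as.data.table(tables$vital_status)
  st[vt, on = "patient_id", death_date := i.death_date]
  st[, censor_date := pmin(res_end, as_day(study_end),
                           data.table::fifelse(is.na(death_date),
                                               as_day(study_end), death_date))]
  st[, censor_days := as.numeric(censor_date - start_date)]
  st[, event := is_trd & !is.na(time_to_trd_days) &
        time_to_trd_days <= horizon_days &
        time_to_trd_days <= censor_days]
  st[, time := pmax(0.5, pmin(data.table::fifelse(event, time_to_trd_days,
                                                  Inf),
                              censor_days, horizon_days))]
  st[, `:=`(care_psychiatric = care_setting_at_start == "psychiatric",
            male = sex == "M",
            age = as.numeric(start_date - birth_date) / 365.25,
            prior_episodes = episode_number - 1L)]
  cols <- c("episode_id", "patient_id", "start_date", "madrs",
            "care_psychiatric", "visits_12m", "sleep_3y", "anxiety_3y",
            "substance_3y", "male", "age", "prior_episodes", "event", "time")
  out <- st[, ..cols]
  data.table::setattr(out, "covariates",
                      c("madrs", "care_psychiatric", "visits_12m", "sleep_3y",
                        "anxiety_3y", "substance_3y", "male", "age",
                        "prior_episodes"))
  out[]
}

# Nelson-Aalen cumulative hazard evaluated at each observation's time;
# the standard auxiliary variable for imputation models with survival outcomes
nelson_aalen_at <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  H <- cumsum(fit$n.event / pmax(fit$n.risk, 1))
  idx <- findInterval(time, fit$time)
  c(0, H)[idx + 1]
}

# one predictive-mean-matching draw for y given design X (no intercept col)
pmm_draw <- function(y, X, miss, k = 5L, bounds = NULL) {
  Xo <- cbind(1, X[!miss, , drop = FALSE])
  yo <- y[!miss]
  Xm <- cbind(1, X[miss, , drop = FALSE])
  qr_ <- qr(Xo)
  beta <- qr.coef(qr_, yo)
  beta[is.na(beta)] <- 0
  res <- yo - as.vector(Xo %*% beta)
  df <- max(length(yo) - ncol(Xo), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qr_)
  ok <- colSums(abs(R)) > 0
  V <- tryCatch(chol2inv(R), error = function(e) NULL)
  beta_star <- beta
  if (!is.null(V)) {
    pert <- tryCatch(t(chol(sigma2 * (V + t(V)) / 2)) %*%
                       stats::rnorm(ncol(Xo)),
                     error = function(e) rep(0, ncol(Xo)))
    beta_star <- beta + as.vector(pert)
  }
  pred_o <- as.vector(Xo %*% beta)
  pred_m <- as.vector(Xm %*% beta_star)
  ord <- order(pred_o)
  po <- pred_o[ord]
  yo_s <- yo[ord]
  n_o <- length(po)
  pos <- findInterval(pred_m, po)
  win <- pmin(k, n_o)
  draws <- numeric(length(pred_m))
  for (i in seq_along(pred_m)) {
    lo <- max(1L, pos[i] - win)
    hi <- min(n_o, pos[i] + win)
    cand <- lo:hi
    d <- abs(po[cand] - pred_m[i])
    sel <- cand[order(d)[seq_len(min(win, length(cand)))]]
    draws[i] <- yo_s[sel[sample.int(length(sel), 1L)]]
  }
  if (!is.null(bounds)) draws <- pmin(bounds[2], pmax(bounds[1], draws))
  draws
}

#' Multiple imputation by chained equations
#'
#' Fills missing values in the designated feature columns by
#' predictive-mean-matching chained equations, conditioning each imputation
#' model on all other candidate features, the outcome indicator and the
#' Nelson-Aalen cumulative hazard at the outcome time (standard practice for
#' survival outcomes). Bounded scores are clipped to their range.
#'
#' @param features feature table from [build_features()].
#' @param m number of completed data sets.
#' @param seed RNG seed; identical seeds give identical imputations.
#' @param covariates candidate feature columns (default: the table's
#'   `covariates` attribute).
#' @param bounds named list of c(min, max) bounds per imputed column
#'   (default clips MADRS-S to 0-54).
#' @param cycles chained-equation cycles per data set.
#' @param pmm_k donors per predictive-mean-matching draw.
#' @return list of `m` completed data.tables (class `trd_imputations`).
#' @export
impute_missing <- function(features, m = 100L, seed = 1L,
                           covariates = attr(features, "covariates"),
                           bounds = list(madrs = c(0, 54)),
                           cycles = 5L, pmm_k = 5L) {
  ft <- data.table::as.data.table(features)
  if (is.null(covariates))
    stop_field("covariates", "not given and no covariates attribute found")
  miss_cols <- covariates[vapply(covariates, function(cn) anyNA(ft[[cn]]),
                                 logical(1))]
  for (cn in miss_cols) {
    if (all(is.na(ft[[cn]])))
      stop(sprintf("column '%s' is fully missing; imputation model is inestimable",
                   cn), call. = FALSE)
  }
  if (!length(miss_cols)) {
    out <- lapply(seq_len(m), function(i) data.table::copy(ft))
    return(structure(out, class = "trd_imputations", covariates = covariates))
  }
  set.seed(seed)
  na_haz <- nelson_aalen_at(ft$time, ft$event)
  # with a single incomplete column the chained equations converge in one
  # pass (its conditioning set never changes)
  n_cycles <- if (length(miss_cols) == 1L) 1L else cycles
  out <- vector("list", m)
  for (im in seq_len(m)) {
    d <- data.table::copy(ft)
    # initial fill: random draws from the observed values
    for (cn in miss_cols) {
      miss <- is.na(d[[cn]])
      obs <- d[[cn]][!miss]
      data.table::set(d, which(miss), cn,
                      obs[sample.int(length(obs), sum(miss), replace = TRUE)])
    }
    for (cy in seq_len(n_cycles)) {
      for (cn in miss_cols) {
        miss <- is.na(ft[[cn]])
        preds <- setdiff(covariates, cn)
        X <- cbind(as.matrix(d[, lapply(.SD, as.numeric), .SDcols = preds]),
                   event = as.numeric(d$event), na_haz = na_haz)
        y <- as.numeric(ft[[cn]])
        y[miss] <- NA
        draws <- pmm_draw(y, X, miss, k = pmm_k, bounds = bounds[[cn]])
        data.table::set(d, which(miss), cn, draws)
      }
    }
    out[[im]] <- d
  }
  structure(out, class = "trd_imputations", covariates = covariates)
}

#' Rubin's rules pooling
#'
#' Pools per-imputation estimates: pooled coefficients are the mean,
#' and the pooled covariance is the mean within-imputation covariance plus
#' `(1 + 1/m)` times the between-imputation covariance.
#'
#' @param coefs m x p matrix of per-imputation coefficient vectors.
#' @param vcovs list of m per-imputation covariance matrices.
#' @return list with `coefficients`, `vcov`, `within`, `between`, `m`.
#' @export
pool_rubin <- function(coefs, vcovs) {
  m <- nrow(coefs)
  qbar <- colMeans(coefs)
  ubar <- Reduce(`+`, vcovs) / m
  B <- if (m > 1) stats::cov(coefs) else matrix(0, ncol(coefs), ncol(coefs))
  total <- ubar + (1 + 1 / m) * B
  dimnames(total) <- list(colnames(coefs), colnames(coefs))
  list(coefficients = qbar, vcov = total, within = ubar, between = B, m = m)
}

#' Fit the full Cox model across completed data sets
#'
#' Fits a Cox proportional hazards model of time-to-TRD (administratively
#' censored at the horizon) on all candidate variables in each completed
#' data set and pools coefficients and variances by Rubin's rules.
#'
#' @param imputations list of completed tables ([impute_missing()]), or a
#'   single data.table for a complete-case fit.
#' @param covariates model variables (default: `covariates` attribute).
#' @return object of class `pooled_cox`: pooled `coefficients`, `vcov`,
#'   per-imputation results, number dropped for non-convergence.
#' @export
fit_full_model <- function(imputations,
                           covariates = attr(imputations, "covariates")) {
  if (is.data.frame(imputations)) imputations <- list(imputations)
  if (is.null(covariates)) covariates <- attr(imputations[[1]], "covariates")
  if (is.null(covariates)) stop_field("covariates", "must be supplied")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fits <- lapply(imputations, function(d) {
    f <- suppressWarnings(
      tryCatch(survival::coxph(fml, data = d, ties = "efron"),
               error = function(e) NULL))
    if (!is.null(f) && any(is.na(stats::coef(f)))) f <- NULL
    f
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no imputation yielded a converged Cox fit", call. = FALSE)
  if (mean(!ok) > 0.20)
    stop(sprintf("%.0f%% of imputations failed to converge",
                 100 * mean(!ok)), call. = FALSE)
  fits <- fits[ok]
  coefs <- do.call(rbind, lapply(fits, stats::coef))
  vcovs <- lapply(fits, stats::vcov)
  pooled <- pool_rubin(coefs, vcovs)
  structure(list(coefficients = pooled$coefficients, vcov = pooled$vcov,
                 within = pooled$within, between = pooled$between,
                 m = length(fits), n_dropped = sum(!ok),
                 covariates = covariates, fits = fits),
            class = "pooled_cox")
}

#' @export
print.pooled_cox <- function(x, ...) {
  cat(sprintf("Pooled Cox model (%d imputations, %d dropped)\n",
              x$m, x$n_dropped))
  se <- sqrt(diag(x$vcov))
  print(round(cbind(coef = x$coefficients, `HR` = exp(x$coefficients),
                    se = se, z = x$coefficients / se), 3))
  invisible(x)
}

#' Step-down approximation of the full model
#'
#' Ranks variables by their contribution to the full model's linear
#' predictor and retains the smallest set whose ordinary-least-squares
#' approximation of the full linear predictor achieves at least `threshold`
#' explained variation; reduced coefficients are re-estimated by regressing
#' the full linear predictor on the retained variables.
#'
#' @param full a `pooled_cox` fit.
#' @param data reference completed data set used to evaluate the linear
#'   predictor.
#' @param threshold required explained variation, in (0, 1].
#' @return object of class `reduced_cox`: retained `variables`,
#'   approximation `coefficients` (with intercept), `achieved` fraction,
#'   elimination `trace`.
#' @export
reduce_model <- function(full, data, threshold = 0.95) {
  stopifnot(inherits(full, "pooled_cox"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop_field("threshold", "must be in (0, 1]")
  X <- as.matrix(data.table::as.data.table(data)[, lapply(.SD, as.numeric),
                                                 .SDcols = full$covariates])
  lp <- as.vector(X %*% full$coefficients)
  tss <- sum((lp - mean(lp))^2)
  r2 <- function(vars) {
    f <- stats::lm.fit(cbind(1, X[, vars, drop = FALSE]), lp)
    1 - sum(f$residuals^2) / tss
  }
  keep <- full$covariates
  trace <- data.table::data.table(dropped = character(0), r2_after = numeric(0))
  repeat {
    if (length(keep) <= 1L) break
    r2s <- vapply(keep, function(v) r2(setdiff(keep, v)), numeric(1))
    best <- which.max(r2s)
    if (r2s[best] >= threshold - 1e-12) {
      trace <- rbind(trace,
                     data.table::data.table(dropped = keep[best],
                                            r2_after = r2s[best]))
      keep <- setdiff(keep, keep[best])
    } else break
  }
  f <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, keep, drop = FALSE]), lp)
  achieved <- 1 - sum(f$residuals^2) / tss
  structure(list(variables = keep, coefficients = f$coefficients,
                 achieved = achieved, trace = trace, full = full),
            class = "reduced_cox")
}

#' @export
print.reduced_cox <- function(x, ...) {
  cat(sprintf("Reduced model: %d of %d variables, approximating %.1f%% of the full model\n",
              length(x$variables), length(x$full$covariates),
              100 * x$achieved))
  print(round(x$coefficients, 3))
  invisible(x)
}

# linear predictor of a reduced model on new data
reduced_lp <- function(reduced, data) {
  X <- as.matrix(data.table::as.data.table(data)[, lapply(.SD, as.numeric),
                                                 .SDcols = reduced$variables])
  as.vector(reduced$coefficients[1] +
              X %*% reduced$coefficients[-1])
}

#' Harrell's concordance index
#'
#' Probability that, among comparable (usable) pairs under censoring, the
#' subject with the earlier event has the higher risk score.
#'
#' @param time,event survival outcome.
#' @param score risk score (higher = higher risk).
#' @return concordance index in [0, 1].
#' @export
concordance_index <- function(time, event, score) {
  fit <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)
  unname(fit$concordance)
}

#' Bootstrap validation of the risk model
#'
#' Apparent Harrell C of the reduced model, optimism estimated by the
#' refit-and-test bootstrap (refit the reduced Cox model on each bootstrap
#' resample, score the original sample), and a calibration table of
#' observed (Kaplan-Meier) versus mean predicted risk at the horizon by
#' risk decile.
#'
#' @param reduced a `reduced_cox` model.
#' @param data reference completed data set.
#' @param n_boot bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param horizon_days risk horizon for calibration.
#' @return list: `c_apparent`, `c_corrected`, `optimism`, `calibration`.
#' @export
validate_model <- function(reduced, data, n_boot = 200L, seed = 1L,
                           horizon_days = 365) {
  stopifnot(inherits(reduced, "reduced_cox"))
  if (!is.numeric(n_boot) || n_boot < 2) stop_field("n_boot", "must be >= 2")
  d <- data.table::as.data.table(data)
  set.seed(seed)
  lp <- reduced_lp(reduced, d)
  c_app <- concordance_index(d$time, d$event, lp)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(reduced$variables, collapse = " + ")))
  opt <- numeric(n_boot)
  n <- nrow(d)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    db <- d[idx]
    fb <- tryCatch(survival::coxph(fml, data = db, ties = "efron"),
                   error = function(e) NULL)
    if (is.null(fb)) { opt[b] <- NA_real_; next }
    Xb <- as.matrix(db[, lapply(.SD, as.numeric), .SDcols = reduced$variables])
    Xo <- as.matrix(d[, lapply(.SD, as.numeric), .SDcols = reduced$variables])
    cb <- concordance_index(db$time, db$event,
                            as.vector(Xb %*% stats::coef(fb)))
    co <- concordance_index(d$time, d$event,
                            as.vector(Xo %*% stats::coef(fb)))
    opt[b] <- cb - co
  }
  optimism <- mean(opt, na.rm = TRUE)

  risk <- predict_risk_from_lp(lp, d, horizon_days)
  dec <- cut(rank(risk, ties.method = "first"),
             breaks = stats::quantile(rank(risk, ties.method = "first"),
                                      probs = seq(0, 1, 0.1)),
             include.lowest = TRUE, labels = FALSE)
  cal <- data.table::rbindlist(lapply(sort(unique(dec)), function(g) {
    rows <- dec == g
    km <- survival::survfit(survival::Surv(time, event) ~ 1, data = d[rows])
    s <- summary(km, times = min(horizon_days, max(km$time)), extend = TRUE)
    data.table::data.table(decile = g, n = sum(rows),
                           predicted = mean(risk[rows]),
                           observed = 1 - s$surv[1])
  }))
  list(c_apparent = c_app, c_corrected = c_app - optimism,
       optimism = optimism, calibration = cal[])
}

# 1 - S0(h)^exp(lp), with S0 from a baseline fit treating lp as offset
predict_risk_from_lp <- function(lp, data, horizon_days) {
  lpc <- lp - mean(lp)
  f0 <- survival::coxph(survival::Surv(time, event) ~ 1 + offset(lpc),
                        data = data)
  bh <- survival::basehaz(f0, centered = FALSE)
  H0 <- stats::approx(c(0, bh$time), c(0, bh$hazard), xout = horizon_days,
                      rule = 2)$y
  1 - exp(-H0 * exp(lpc))
}
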