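#' Follow-up and censoring dates for matched episodes
#'
#' Follow-up starts at the index date and ends at the first of: emigration
#' (end of residency), death, the first post-index record of an exclusion
#' diagnosis, or the administrative end of follow-up.
#'
#' @param matched output of [assign_index_dates()].
#' @param tables registry tables (needs `demographics`, `vital_status`,
#'   `diagnoses`).
#' @param study_end administrative end of follow-up.
#' @param exclusion_codes ICD-10 prefixes censoring follow-up when first
#'   recorded after the index date.
#' @return the matched table with `death_date`, `censor_date` (end of
#'   at-risk time excluding death) appended.
#' @keywords internal
followup_frame <- function(matched, tables, study_end = "2018-12-31",
                           exclusion_codes = default_exclusion_codes()) {
  study_end <- as_day(study_end)
  fu <- data.table::as.data.table(matched)
  dem <- data.table::as.data.table(tables$demographics)
  fu[dem, on = "patient_id", res_end := i.residency_end]
  fu[data.table::as.data.table(tables$vital_status), on = "patient_id",
     death_date := i.death_date]
  dx <- data.table::as.data.table(tables$diagnoses)
  excl <- dx[code_matches(icd10, exclusion_codes),
             .(patient_id, date)]
  if (nrow(excl)) {
    ex1 <- excl[fu[, .(patient_id, episode_id, index_date)],
                on = .(patient_id, date > index_date),
                .(episode_id = i.episode_id, excl_date = x.date)]
    ex1 <- ex1[!is.na(excl_date)]
    if (nrow(ex1)) {
      ex1 <- ex1[, .(excl_date = min(excl_date)), by = episode_id]
      fu[ex1, on = "episode_id", excl_date := i.excl_date]
    }
  }
  if (!"excl_date" %in% names(fu)) fu[, excl_date := as.Date(NA)]
  fu[, censor_date := pmin(res_end, study_end,
                           data.table::fifelse(is.na(excl_date), study_end,
                                               excl_date))]
  fu
}

#' Cox survival contrast between TRD and matched non-TRD episodes
#'
#' Fits a Cox proportional hazards model (Efron ties) of the outcome on the
#' TRD indicator with a cluster-robust (sandwich) variance using the patient
#' as cluster, starting follow-up at the index date. For intentional
#' self-harm only inpatient and psychiatric (specialised) outpatient records
#' qualify as events. Event counts, person-years and rates per 1000
#' person-years are reported per group.
#'
#' @param matched output of [assign_index_dates()].
#' @param tables registry tables (demographics, vital_status, diagnoses).
#' @param outcome `"mortality"` (all-cause death) or `"self_harm"`
#'   (first ICD-10 X60-X84 record after index).
#' @param study_end administrative end of follow-up.
#' @param exclusion_codes censoring diagnosis prefixes.
#' @return object of class `trd_survival`: hazard ratio with 95% CI,
#'   per-group event counts/person-years/rates, the fitted model, and an
#'   `inestimable` flag (zero events in both arms).
#' @export
fit_survival <- function(matched, tables,
                         outcome = c("mortality", "self_harm"),
                         study_end = "2018-12-31",
                         exclusion_codes = default_exclusion_codes()) {
  outcome <- match.arg(outcome)
  fu <- followup_frame(matched, tables, study_end, exclusion_codes)
  if (outcome == "mortality") {
    fu[, event_date := death_date]
  } else {
    dx <- data.table::as.data.table(tables$diagnoses)
    sh <- dx[code_matches(icd10, paste0("X", 60:84)) &
               (locus == "inpatient" |
                  (locus == "outpatient" & care_setting == "psychiatric")),
             .(patient_id, date)]
    fu[, event_date := as.Date(NA)]
    if (nrow(sh)) {
      s1 <- sh[fu[, .(patient_id, episode_id, index_date)],
               on = .(patient_id, date > index_date),
               .(episode_id = i.episode_id, ev = x.date)]
      s1 <- s1[!is.na(ev)]
      if (nrow(s1)) {
        s1 <- s1[, .(ev = min(ev)), by = episode_id]
        fu[s1, on = "episode_id", event_date := i.ev]
      }
    }
    # death censors self-harm follow-up
    fu[, censor_date := pmin(censor_date,
                             data.table::fifelse(is.na(death_date), censor_date,
                                                 death_date))]
  }
  fu[, end_date_fu := pmin(censor_date,
                           data.table::fifelse(is.na(event_date), censor_date,
                                               event_date))]
  fu[, event := !is.na(event_date) & event_date <= censor_date]
  fu[, time := pmax(0.5, as.numeric(end_date_fu - index_date))]

  grp <- fu[, .(events = sum(event), person_years = sum(time) / 365.25),
            by = .(group = data.table::fifelse(is_trd, "TRD", "non-TRD"))]
  grp[, rate_per_1000py := 1000 * events / person_years]
  data.table::setorder(grp, group)

  if (sum(fu$event) == 0L) {
    return(structure(list(outcome = outcome, inestimable = TRUE,
                          hr = NA_real_, ci = c(NA_real_, NA_real_),
                          groups = grp[], model = NULL, data = fu[]),
                     class = "trd_survival"))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ is_trd,
                         data = fu, ties = "efron",
                         cluster = patient_id, robust = TRUE)
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]     # robust (sandwich) variance
  structure(list(outcome = outcome, inestimable = FALSE,
                 hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 se_log_hr = se, groups = grp[], model = fit, data = fu[]),
            class = "trd_survival")
}

#' @export
print.trd_survival <- function(x, ...) {
  cat(sprintf("Cox contrast, outcome: %s\n",
              ifelse(x$outcome == "mortality", "all-cause mortality",
                     "intentional self-harm")))
  if (x$inestimable) {
    cat("  inestimable: no events in either arm\n")
  } else {
    cat(sprintf("  HR %.2f (95%% CI %.2f-%.2f), cluster-robust\n",
                x$hr, x$ci[1], x$ci[2]))
  }
  print(x$groups)
  invisible(x)
}

#' Monthly cumulative comorbidity proportions around the index date
#'
#' For each condition and group, the proportion of episodes whose patient
#' had a first qualifying diagnosis in any 30-day month bin up to and
#' including month `m` relative to the index date (carry-forward), for
#' months -12 to +12.
#'
#' @param matched output of [assign_index_dates()].
#' @param diagnoses diagnosis table.
#' @param conditions named list of ICD-10 prefix vectors
#'   (default: anxiety, stress, sleep disorder, substance use).
#' @param months month offsets to report.
#' @param bin_days days per month bin (30-day bins anchored at the index).
#' @return data.table: `condition`, `group`, `month`, `proportion`, `n`.
#' @export
cumulative_comorbidity_series <- function(matched, diagnoses,
                                          conditions = default_comorbidity_codes()[
                                            c("anxiety", "stress",
                                              "sleep_disorder", "substance_use")],
                                          months = -12:12, bin_days = 30L) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop_field("conditions", "must be a named list of code prefixes")
  mt <- data.table::as.data.table(matched)
  dx <- data.table::as.data.table(diagnoses)
  out <- list()
  for (cond in names(conditions)) {
    hits <- dx[code_matches(icd10, conditions[[cond]])]
    d <- mt[, .(episode_id, patient_id, index_date,
                group = data.table::fifelse(is_trd, "TRD", "non-TRD"))]
    d[, first_dx := as.Date(NA)]
    if (nrow(hits)) {
      first <- hits[, .(first_dx = min(date)), by = patient_id]
      d[first, on = "patient_id", first_dx := i.first_dx]
    }
    d[, first_month := floor(as.numeric(first_dx - index_date) / bin_days)]
    res <- d[, {
      n <- .N
      lapply(stats::setNames(months, months),
             function(mm) mean(!is.na(first_month) & first_month <= mm))
    }, by = group]
    res <- data.table::melt(res, id.vars = "group", variable.name = "month",
                            value.name = "proportion")
    res[, month := as.integer(as.character(month))]
    res[, condition := cond]
    res[d[, .N, by = group], on = "group", n := i.N]
    out[[cond]] <- res
  }
  out <- data.table::rbindlist(out, use.names = TRUE)
  data.table::setcolorder(out, c("condition", "group", "month", "proportion", "n"))
  data.table::setorder(out, condition, group, month)
  out[]
}

#' Monthly mean utilization / lost-workday series around the index date
#'
#' Mean outpatient physician visits, inpatient bed-days, or lost workdays
#' per 30-day month bin from -12 to +12 around the index date, by group,
#' plus 12-month before/after aggregates (the after window includes the
#' index month). Lost workdays are restricted to patients aged 20-64 at the
#' index date and sick-leave spells of at least 14 days; spell days are
#' apportioned to the bins they overlap. Bed-days likewise apportion
#' admission-to-discharge stays.
#'
#' @param matched output of [assign_index_dates()].
#' @param tables registry tables (`diagnoses`, `sick_leave`, `demographics`).
#' @param metric one of `"outpatient_visits"`, `"inpatient_bed_days"`,
#'   `"lost_workdays"`.
#' @param months month offsets to report.
#' @param bin_days days per month bin.
#' @param min_spell_days sick-leave spells shorter than this are ignored.
#' @param workday_ages inclusive age range for the lost-workday analysis.
#' @return list with `series` (group, month, mean, n) and `aggregates`
#'   (group, window, mean).
#' @export
monthly_mean_series <- function(matched, tables,
                                metric = c("outpatient_visits",
                                           "inpatient_bed_days",
                                           "lost_workdays"),
                                months = -12:12, bin_days = 30L,
                                min_spell_days = 14L,
                                workday_ages = c(20, 64)) {
  metric <- match.arg(metric)
  mt <- data.table::as.data.table(matched)
  mt <- mt[, .(episode_id, patient_id, index_date,
               group = data.table::fifelse(is_trd, "TRD", "non-TRD"))]
  if (metric == "lost_workdays") {
    dem <- data.table::as.data.table(tables$demographics)
    mt[dem, on = "patient_id", birth_date := i.birth_date]
    mt[, age_at_index := as.numeric(index_date - birth_date) / 365.25]
    mt <- mt[age_at_index >= workday_ages[1] & age_at_index <= workday_ages[2]]
  }
  lo <- min(months) * bin_days
  hi <- (max(months) + 1L) * bin_days - 1L

  if (metric == "outpatient_visits") {
    dx <- data.table::as.data.table(tables$diagnoses)[locus == "outpatient"]
    hits <- dx[mt, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL,
               .(episode_id = i.episode_id, group = i.group,
                 off = as.numeric(x.date - i.index_date))]
    hits <- hits[off >= lo & off <= hi]
    hits[, month := floor(off / bin_days)]
    counts <- hits[, .(total = .N), by = .(episode_id, group, month)]
  } else {
    if (metric == "inpatient_bed_days") {
      sp <- data.table::as.data.table(tables$diagnoses)[locus == "inpatient" &
                                                          !is.na(discharge_date),
                                                        .(patient_id,
                                                          s = date,
                                                          e = discharge_date)]
    } else {
      sp <- data.table::as.data.table(tables$sick_leave)
      sp <- sp[as.numeric(end_date - start_date) + 1 >= min_spell_days,
               .(patient_id, s = start_date, e = end_date)]
    }
    spans <- sp[mt, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL,
                .(episode_id = i.episode_id, group = i.group,
                  s = as.numeric(x.s - i.index_date),
                  e = as.numeric(x.e - i.index_date))]
    spans <- spans[e >= lo & s <= hi]
    if (nrow(spans)) {
      spans[, `:=`(b0 = pmax(floor(s / bin_days), min(months)),
                   b1 = pmin(floor(e / bin_days), max(months)))]
      reps <- spans$b1 - spans$b0 + 1L
      i2 <- rep(seq_len(nrow(spans)), reps)
      bins <- spans$b0[i2] + sequence(reps) - 1L
      days <- pmin(spans$e[i2], (bins + 1) * bin_days - 1) -
        pmax(spans$s[i2], bins * bin_days) + 1
      counts <- data.table::data.table(episode_id = spans$episode_id[i2],
                                       group = spans$group[i2],
                                       month = bins, total = days)
      counts <- counts[, .(total = sum(total)), by = .(episode_id, group, month)]
    } else {
      counts <- data.table::data.table(episode_id = integer(0),
                                       group = character(0),
                                       month = integer(0), total = numeric(0))
    }
  }
  denom <- mt[, .(n = .N), by = group]
  grid <- data.table::CJ(group = denom$group, month = months)
  tot <- counts[, .(sum_total = sum(total)), by = .(group, month)]
  series <- tot[grid, on = .(group, month)]
  series[is.na(sum_total), sum_total := 0]
  series[denom, on = "group", n := i.n]
  series[, mean := sum_total / n]
  series[, sum_total := NULL]
  data.table::setorder(series, group, month)

  agg <- series[, .(mean = sum(mean[month < 0])), by = group]
  agg[, window := "12m_before"]
  agg2 <- series[, .(mean = sum(mean[month >= 0])), by = group]
  agg2[, window := "12m_after"]
  aggregates <- data.table::rbindlist(list(agg, agg2), use.names = TRUE)
  data.table::setcolorder(aggregates, c("group", "window", "mean"))
  list(series = series[], aggregates = aggregates[])
}

#' Kaplan-Meier episode duration by TRD status
#'
#' Episode duration (start to last depression-related event) for episodes of
#' patients with at least `min_followup_days` of follow-up from episode
#' start; an episode still accruing events at the end of observation is
#' censored at the end of its patient's observation.
#'
#' @param status classified episode table.
#' @param tables registry tables (`demographics`, `vital_status`).
#' @param min_followup_days follow-up required from episode start.
#' @param study_end administrative end of follow-up.
#' @param closure_gap_days quiet time needed after the last event before the
#'   episode end is considered observed rather than censored.
#' @return list with `km` (time, n_risk, n_event, surv, group) and `fit`.
#' @export
km_episode_duration <- function(status, tables, min_followup_days = 365L,
                                study_end = "2018-12-31",
                                closure_gap_days = 365L) {
  st <- data.table::as.data.table(status)
  dem <- data.table::as.data.table(tables$demographics)
  st[dem, on = "patient_id", res_end := i.residency_end]
  st[data.table::as.data.table(tables$vital_status), on = "patient_id",
     death_date := i.death_date]
  st[, obs_end := pmin(res_end, as_day(study_end),
                       data.table::fifelse(is.na(death_date), as_day(study_end),
                                           death_date))]
  st <- st[as.numeric(obs_end - start_date) >= min_followup_days]
  if (!nrow(st)) return(list(km = NULL, fit = NULL))
  st[, closed := as.numeric(obs_end - end_date) >= closure_gap_days]
  st[, dur := data.table::fifelse(closed,
                                  as.numeric(end_date - start_date),
                                  as.numeric(obs_end - start_date))]
  st[, dur := pmax(0.5, dur)]
  st[, group := data.table::fifelse(is_trd, "TRD", "non-TRD")]
  fit <- survival::survfit(survival::Surv(dur, closed) ~ group, data = st)
  strata <- if (is.null(fit$strata)) {
    rep(unique(st$group), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  km <- data.table::data.table(group = strata, time = fit$time,
                               n_risk = fit$n.risk, n_event = fit$n.event,
                               surv = fit$surv)
  list(km = km[], fit = fit)
}

#' Inter-trial interval and time-to-TRD summaries
#'
#' Median and interquartile range of the intervals episode start to first
#' trial, first to second, second to third, and (for TRD episodes) episode
#' start to TRD index.
#'
#' @param trials output of [identify_trials()].
#' @param status classified episode table.
#' @return data.table: `interval`, `n`, `median_days`, `q1_days`, `q3_days`.
#' @export
trial_interval_summary <- function(trials, status) {
  tr <- data.table::as.data.table(trials)
  st <- data.table::as.data.table(status)
  wide <- data.table::dcast(tr[trial_index <= 3L],
                            episode_id ~ trial_index,
                            value.var = "initiation_date")
  data.table::setnames(wide, as.character(1:3)[as.character(1:3) %in% names(wide)],
                       paste0("t", (1:3)[as.character(1:3) %in% names(wide)]))
  for (cn in c("t1", "t2", "t3"))
    if (!cn %in% names(wide)) wide[, (cn) := as.Date(NA)]
  wide[st, on = "episode_id", start_date := i.start_date]
  ivs <- list(
    start_to_first = as.numeric(wide$t1 - wide$start_date),
    first_to_second = as.numeric(wide$t2 - wide$t1),
    second_to_third = as.numeric(wide$t3 - wide$t2),
    start_to_trd = st[is_trd == TRUE, time_to_trd_days])
  out <- data.table::rbindlist(lapply(names(ivs), function(nm) {
    v <- ivs[[nm]]
    v <- v[!is.na(v)]
    q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    else rep(NA_real_, 3)
    data.table::data.table(interval = nm, n = length(v), median_days = q[2],
                           q1_days = q[1], q3_days = q[3])
  }))
  out[]
}
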