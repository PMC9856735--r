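origin <- as.Date("2015-01-01")

empty_tables <- function(n_pat, study_end = "2018-12-31") {
  list(demographics = data.frame(patient_id = seq_len(n_pat),
                                 birth_date = origin - 40 * 365,
                                 sex = "F", ses = 1L,
                                 residency_start = as.Date("2010-01-01"),
                                 residency_end = as.Date(study_end)),
       vital_status = data.frame(patient_id = seq_len(n_pat),
                                 death_date = as.Date(NA)),
       diagnoses = data.frame(patient_id = integer(0),
                              date = as.Date(character(0)),
                              icd10 = character(0),
                              care_setting = character(0),
                              locus = character(0),
                              discharge_date = as.Date(character(0))),
       sick_leave = data.frame(patient_id = integer(0),
                               start_date = as.Date(character(0)),
                               end_date = as.Date(character(0))))
}

test_that("person-years bookkeeping is an exact identity", {
  mm <- tiny_matched(15)
  tabs <- empty_tables(max(mm$patient_id))
  # deaths in both arms (patients 1 and 4 are cases)
  tabs$vital_status$death_date[c(1, 2, 4, 8)] <- origin + 300
  sv <- fit_survival(mm, tabs)
  expect_equal(sum(sv$groups$person_years), sum(sv$data$time) / 365.25)
  by_grp <- tapply(sv$data$time, sv$data$is_trd, sum) / 365.25
  expect_equal(sort(as.numeric(by_grp)), sort(sv$groups$person_years))
  expect_equal(sv$groups$rate_per_1000py,
               1000 * sv$groups$events / sv$groups$person_years)
})

test_that("label-symmetric arms give HR near 1 and zero events are flagged", {
  set.seed(77)
  n <- 400
  mm <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(set_id = i, episode_id = i, patient_id = i,
               role = ifelse(i %% 2 == 0, "case", "control"),
               is_trd = i %% 2 == 0, start_date = origin,
               end_date = origin + 600, index_date = origin + 100)))
  tabs <- empty_tables(n)
  dead <- sample(n, 60)     # deaths assigned independently of the label
  tabs$vital_status$death_date[dead] <- origin + 100 +
    sample(50:1200, 60, TRUE)
  sv <- fit_survival(mm, tabs)
  expect_false(sv$inestimable)
  expect_true(sv$ci[1] < 1 && 1 < sv$ci[2])

  sv0 <- fit_survival(mm, empty_tables(n))
  expect_true(sv0$inestimable)
  expect_true(is.na(sv0$hr))
})

test_that("self-harm events qualify only from inpatient or psychiatric outpatient care", {
  mm <- tiny_matched(2)   # 6 episodes, index at origin+100
  tabs <- empty_tables(6)
  tabs$diagnoses <- data.frame(
    patient_id = c(1L, 2L, 3L),
    date = origin + 200,
    icd10 = "X64",
    care_setting = c("psychiatric", "nonpsychiatric", "nonpsychiatric"),
    locus = c("outpatient", "outpatient", "inpatient"),
    discharge_date = as.Date(NA))
  sv <- fit_survival(mm, tabs, outcome = "self_harm")
  ev <- sv$data[sv$data$event, ]
  expect_equal(sort(ev$patient_id), c(1L, 3L))   # primary-care record ignored
})

test_that("comorbidity series is carry-forward and monotone", {
  mm <- tiny_matched(5)   # 15 episodes
  tabs <- empty_tables(15)
  # flat zero without diagnoses
  s0 <- cumulative_comorbidity_series(mm, tabs$diagnoses,
                                      conditions = list(anxiety = "F41"))
  expect_true(all(s0$proportion == 0))
  # one control diagnosed 3 months before index steps the series at -3
  dx <- data.frame(patient_id = 2L, date = origin + 100 - 90, icd10 = "F41.1",
                   care_setting = "psychiatric", locus = "outpatient",
                   discharge_date = as.Date(NA))
  s1 <- cumulative_comorbidity_series(mm, dx,
                                      conditions = list(anxiety = "F41"))
  ctrl <- s1[s1$group == "non-TRD", ]
  n_ctrl <- ctrl$n[1]
  expect_equal(ctrl$proportion[ctrl$month < -3], rep(0, sum(ctrl$month < -3)))
  expect_equal(ctrl$proportion[ctrl$month >= -3],
               rep(1 / n_ctrl, sum(ctrl$month >= -3)))
  # monotone within every condition x group
  co <- simulate_cohort(sim_config(n_patients = 800, seed = 12))
  cl <- run_classification(co$tables)
  mt <- match_episodes(cl$status, co$tables$demographics, seed = 1)
  mm2 <- assign_index_dates(mt, cl$status)
  ser <- cumulative_comorbidity_series(mm2, co$tables$diagnoses)
  for (key in split(ser, paste(ser$condition, ser$group))) {
    expect_true(all(diff(key$proportion[order(key$month)]) >= 0))
    expect_true(all(key$proportion >= 0 & key$proportion <= 1))
  }
  expect_error(cumulative_comorbidity_series(mm, tabs$diagnoses,
                                             conditions = list("F41")),
               "conditions")
})

test_that("lost workdays respect the spell floor, age filter and apportionment", {
  mm <- tiny_matched(1)  # 3 episodes, patients 1..3, index origin+100
  tabs <- empty_tables(3)
  # 10-day spell: below the 14-day floor, contributes nothing
  tabs$sick_leave <- data.frame(patient_id = 1L, start_date = origin + 110,
                                end_date = origin + 119)
  r0 <- monthly_mean_series(mm, tabs, "lost_workdays")
  expect_true(all(r0$series$mean == 0))
  # a 30-day spell split 20/10 across two month bins
  # bin 0 covers offsets 100..129 relative to index at origin+100
  tabs$sick_leave <- data.frame(patient_id = 1L, start_date = origin + 110,
                                end_date = origin + 139)
  r1 <- monthly_mean_series(mm, tabs, "lost_workdays")
  s <- r1$series[r1$series$group == "TRD", ]
  expect_equal(s$mean[s$month == 0], 20 / 1)
  expect_equal(s$mean[s$month == 1], 10 / 1)
  # a 67-year-old leaves the denominator entirely
  tabs$demographics$birth_date <- origin - round(67 * 365.25)
  r2 <- monthly_mean_series(mm, tabs, "lost_workdays")
  expect_equal(nrow(r2$series), 0L)
})

test_that("bed-days apportion admission-to-discharge stays", {
  mm <- tiny_matched(1)
  tabs <- empty_tables(3)
  tabs$diagnoses <- data.frame(patient_id = 2L, date = origin + 95,
                               icd10 = "F32.2", care_setting = "psychiatric",
                               locus = "inpatient",
                               discharge_date = origin + 104)
  r <- monthly_mean_series(mm, tabs, "inpatient_bed_days")
  s <- r$series[r$series$group == "non-TRD", ]
  # admission spans offsets -5..4: 5 days in bin -1, 5 in bin 0
  expect_equal(s$mean[s$month == -1], 5 / 2)
  expect_equal(s$mean[s$month == 0], 5 / 2)
  agg <- r$aggregates
  expect_equal(agg$mean[agg$group == "non-TRD" & agg$window == "12m_before"],
               5 / 2)
  expect_equal(agg$mean[agg$group == "non-TRD" & agg$window == "12m_after"],
               5 / 2)
})

test_that("outpatient visit means count events per 30-day bin", {
  mm <- tiny_matched(1)
  tabs <- empty_tables(3)
  tabs$diagnoses <- data.frame(patient_id = 1L,
                               date = origin + 100 + c(0, 5, 40),
                               icd10 = "Z00.0",
                               care_setting = "nonpsychiatric",
                               locus = "outpatient",
                               discharge_date = as.Date(NA))
  r <- monthly_mean_series(mm, tabs, "outpatient_visits")
  s <- r$series[r$series$group == "TRD", ]
  expect_equal(s$mean[s$month == 0], 2)
  expect_equal(s$mean[s$month == 1], 1)
  expect_error(monthly_mean_series(mm, tabs, "bogus"))
})

test_that("the KM estimator matches a brute-force product-limit computation", {
  set.seed(55)
  for (k in 1:20) {
    n <- sample(5:20, 1)
    time <- sample(30:1000, n, replace = TRUE)
    event <- runif(n) < 0.7
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    want <- oracle_km(time, event)
    got <- data.frame(time = fit$time, surv = fit$surv)
    got <- got[got$time %in% want$time, ]
    expect_equal(got$surv, want$surv, tolerance = 1e-12)
  }
})

test_that("episode-duration KM handles degenerate inputs", {
  st <- data.frame(patient_id = 1:20, episode_id = 1:20,
                   start_date = origin, end_date = origin + 100,
                   is_trd = rep(c(TRUE, FALSE), 10))
  tabs <- empty_tables(20)
  km <- km_episode_duration(st, tabs)
  # every episode ends at day 100 with ample quiet follow-up: S drops to 0
  expect_equal(min(km$km$surv), 0)
  expect_true(all(km$km$time == 100))
  # episodes still accruing at the end of observation stay censored at 1
  st2 <- st
  st2$end_date <- as.Date("2018-12-31")
  km2 <- km_episode_duration(st2, tabs)
  expect_true(all(km2$km$surv == 1))
})

test_that("interval summaries report median and IQR per transition", {
  co <- simulate_cohort(sim_config(n_patients = 800, seed = 3))
  cl <- run_classification(co$tables)
  s <- trial_interval_summary(cl$trials, cl$status)
  expect_setequal(s$interval, c("start_to_first", "first_to_second",
                                "second_to_third", "start_to_trd"))
  expect_true(all(s$q1_days <= s$median_days & s$median_days <= s$q3_days,
                  na.rm = TRUE))
  st3 <- s[s$interval == "start_to_trd", ]
  expect_equal(st3$n, sum(cl$status$is_trd))
})
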