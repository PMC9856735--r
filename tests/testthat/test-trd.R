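origin <- as.Date("2015-01-01")

test_that("exposure intervals merge fills within the grace period", {
  # one 100-day fill: interval covers 2015-01-01 .. 2015-04-10
  one <- estimate_exposure(data.frame(patient_id = 1L, date = origin,
                                      atc = "N06AB06", supply_days = 100L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start_date, origin)
  expect_equal(one$end_date, as.Date("2015-04-10"))
  expect_equal(one$duration_days, 100)

  # fills on day 0 and 35 (30-day each), grace 30: one interval [0, 64]
  two <- estimate_exposure(data.frame(patient_id = 1L,
                                      date = origin + c(0, 35),
                                      atc = "N06AB06",
                                      supply_days = c(30L, 30L)))
  expect_equal(nrow(two), 1L)
  expect_equal(as.numeric(two$end_date - origin), 64)

  # a coverage gap beyond the grace splits the exposure
  split <- estimate_exposure(data.frame(patient_id = 1L,
                                        date = origin + c(0, 100),
                                        atc = "N06AB06",
                                        supply_days = c(30L, 30L)))
  expect_equal(nrow(split), 2L)

  expect_error(estimate_exposure(data.frame(patient_id = 1L, date = origin,
                                            atc = "N06AB06",
                                            supply_days = 0L)),
               "supply_days")
})

mk_ep <- function(start = 0, end = 400) {
  data.frame(patient_id = 1L, episode_id = 1L,
             start_date = origin + start, end_date = origin + end)
}

test_that("trial identification applies duration, gap and dose rules", {
  # sertraline 100 d at day 0, fluoxetine 30 d at day 46, ECT at day 60
  disp <- data.frame(patient_id = 1L, date = origin + c(0, 46),
                     atc = c("N06AB06", "N06AB03"),
                     supply_days = c(100L, 30L))
  procs <- data.frame(patient_id = 1L, date = origin + 60, procedure = "ECT")
  tr <- identify_trials(mk_ep(), estimate_exposure(disp), procs)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$trial_index, 1:3)
  expect_equal(tr$treatment_key[3], "ECT")
  expect_equal(as.numeric(tr$initiation_date[3] - origin), 60)

  # a second drug exactly 28 days after the first is not a trial (strict >)
  d28 <- data.frame(patient_id = 1L, date = origin + c(0, 28),
                    atc = c("N06AB06", "N06AB03"), supply_days = c(100L, 30L))
  expect_equal(nrow(identify_trials(mk_ep(), estimate_exposure(d28))), 1L)
  d29 <- data.frame(patient_id = 1L, date = origin + c(0, 29),
                    atc = c("N06AB06", "N06AB03"), supply_days = c(100L, 30L))
  expect_equal(nrow(identify_trials(mk_ep(), estimate_exposure(d29))), 2L)

  # 27-day exposure is too short; 28 days qualifies
  short <- data.frame(patient_id = 1L, date = origin, atc = "N06AB06",
                      supply_days = 27L)
  expect_equal(nrow(identify_trials(mk_ep(), estimate_exposure(short))), 0L)
  exact <- data.frame(patient_id = 1L, date = origin, atc = "N06AB06",
                      supply_days = 28L)
  expect_equal(nrow(identify_trials(mk_ep(), estimate_exposure(exact))), 1L)

  # quetiapine at 100 mg/day is not an add-on trial; above 100 mg it is
  q100 <- data.frame(patient_id = 1L, date = origin, atc = "N05AH04",
                     supply_days = 100L, daily_dose_mg = 100)
  expect_equal(nrow(identify_trials(mk_ep(), estimate_exposure(q100))), 0L)
  q150 <- q100; q150$daily_dose_mg <- 150
  expect_equal(nrow(identify_trials(mk_ep(), estimate_exposure(q150))), 1L)

  # exposures initiated before the episode start never count
  pre <- data.frame(patient_id = 1L, date = origin - 10, atc = "N06AB06",
                    supply_days = 100L)
  expect_equal(nrow(identify_trials(mk_ep(), estimate_exposure(pre))), 0L)
})

test_that("consecutive ECT sessions collapse into one course", {
  procs <- data.frame(patient_id = 1L, date = origin + c(10, 12, 14, 16, 100),
                      procedure = "ECT")
  tr <- identify_trials(mk_ep(), estimate_exposure(NULL), procs)
  expect_equal(nrow(tr), 2L)   # one course at day 10, a second at day 100
  expect_equal(as.numeric(tr$initiation_date - origin), c(10, 100))
  expect_true(all(tr$is_procedure))
})

test_that("TRD classification is the third-trial rule", {
  disp <- data.frame(patient_id = 1L, date = origin + c(0, 165, 362, 500),
                     atc = c("N06AB06", "N06AX11", "N06AB03", "N06AX16"),
                     supply_days = 100L)
  ep <- mk_ep(end = 600)
  tr <- identify_trials(ep, estimate_exposure(disp))
  st <- classify_trd(tr, ep)
  expect_true(st$is_trd)
  expect_equal(st$n_trials, 4L)
  expect_equal(as.numeric(st$index_date - origin), 362)  # third, not fourth
  expect_equal(st$time_to_trd_days, 362)

  st2 <- classify_trd(tr[tr$trial_index <= 2, ], ep)
  expect_false(st2$is_trd)
  expect_true(is.na(st2$index_date))
})

test_that("trial identification agrees with the brute-force day-set oracle", {
  set.seed(99)
  for (k in 1:400) {
    inst <- random_trial_instance()
    got <- run_trials_pkg(inst)
    want <- oracle_trials_one(inst$disp, inst$procs, inst$ep_start, inst$ep_end)
    expect_equal(nrow(got), nrow(want), info = paste("instance", k))
    if (nrow(want)) {
      expect_equal(as.numeric(got$initiation_date - as.Date("2010-01-01")),
                   want$day, info = paste("instance", k))
      expect_equal(got$treatment_key, want$key, info = paste("instance", k))
    }
  }
})

test_that("removing a non-merging dispensation never adds trials", {
  set.seed(1234)
  for (k in 1:60) {
    inst <- random_trial_instance()
    if (is.null(inst$disp) || nrow(inst$disp) < 2) next
    n0 <- nrow(run_trials_pkg(inst))
    # drop a dispensation of a drug with a single fill (removal cannot merge)
    tab <- table(inst$disp$atc)
    singles <- names(tab)[tab == 1]
    if (!length(singles)) next
    inst2 <- inst
    inst2$disp <- inst$disp[inst$disp$atc != singles[1], , drop = FALSE]
    n1 <- nrow(run_trials_pkg(inst2))
    expect_lte(n1, n0)
  }
})

test_that("rule validation names the offending field", {
  expect_error(trd_rules(gap_days = 0), "gap_days")
  expect_error(trd_rules(min_duration_days = -1), "min_duration_days")
})
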