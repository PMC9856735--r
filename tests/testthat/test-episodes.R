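origin <- as.Date("2015-03-01")

mk_events <- function(day, kind, code, patient_id = 1L) {
  data.frame(patient_id = patient_id, date = origin + day, kind = kind,
             code = code, care_setting = "nonpsychiatric",
             locus = "outpatient", supply_days = NA_real_,
             daily_dose_mg = NA_real_, score = NA_real_)
}

test_that("a single diagnosis forms a one-day episode", {
  ep <- build_episodes(mk_events(0, "diagnosis", "F32.0"))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$start_date, origin)
  expect_equal(ep$end_date, origin)
  expect_equal(ep$episode_number, 1L)
})

test_that("the quiet-gap rule splits and chains episodes as specified", {
  # events at 100 and 300 accrete; F33 at day 700 opens a new episode
  ev <- rbind(mk_events(0, "diagnosis", "F32.0"),
              mk_events(100, "dispensation", "N06AB06"),
              mk_events(300, "dispensation", "N06AB06"),
              mk_events(700, "diagnosis", "F33.1"))
  ep <- build_episodes(ev)
  expect_equal(nrow(ep), 2L)
  expect_equal(as.numeric(ep$start_date - origin), c(0, 700))
  expect_equal(as.numeric(ep$end_date - origin), c(300, 700))

  # all gaps < 365: a single episode spanning the chain
  ev2 <- rbind(mk_events(0, "diagnosis", "F32.0"),
               mk_events(200, "dispensation", "N06AB06"),
               mk_events(400, "dispensation", "N06AB06"),
               mk_events(600, "dispensation", "N06AB06"))
  ep2 <- build_episodes(ev2)
  expect_equal(nrow(ep2), 1L)
  expect_equal(as.numeric(c(ep2$start_date, ep2$end_date) - origin), c(0, 600))
})

test_that("non-diagnosis events cannot open an episode and ratings never extend one", {
  ev <- rbind(mk_events(0, "dispensation", "N06AB06"),   # before any diagnosis
              mk_events(50, "diagnosis", "F32.0"),
              mk_events(60, "rating", "MADRS-S"))
  ep <- build_episodes(ev)
  expect_equal(nrow(ep), 1L)
  expect_equal(as.numeric(ep$start_date - origin), 50)
  expect_equal(as.numeric(ep$end_date - origin), 50)
})

test_that("episode construction matches the brute-force oracle on random streams", {
  set.seed(421)
  n_instances <- 400
  evs <- lapply(seq_len(n_instances), function(p) {
    e <- random_event_stream(sample.int(12, 1))
    data.frame(patient_id = p, date = as.Date("2014-01-01") + e$day,
               kind = e$kind, code = e$code, care_setting = "psychiatric",
               locus = "outpatient", supply_days = NA_real_,
               daily_dose_mg = NA_real_, score = NA_real_,
               day = e$day)
  })
  all_ev <- do.call(rbind, evs)
  ep <- build_episodes(all_ev[, setdiff(names(all_ev), "day")])
  codes <- default_episode_codes()
  for (p in seq_len(n_instances)) {
    e <- evs[[p]]
    dep <- (e$kind == "diagnosis" & substr(e$code, 1, 3) %in% c("F32", "F33")) |
      (e$kind == "dispensation" & (startsWith(e$code, "N06A") |
                                     e$code %in% codes$addon_codes)) |
      (e$kind == "procedure" & e$code %in% codes$procedures)
    opens <- e$kind == "diagnosis" & substr(e$code, 1, 3) %in% c("F32", "F33")
    want <- oracle_episodes_one(e$day, opens, dep)
    got <- ep[ep$patient_id == p, ]
    expect_equal(nrow(got), nrow(want), info = paste("patient", p))
    if (nrow(want)) {
      expect_equal(as.numeric(got$start_date - as.Date("2014-01-01")),
                   unname(want[, 1]), info = paste("patient", p))
      expect_equal(as.numeric(got$end_date - as.Date("2014-01-01")),
                   unname(want[, 2]), info = paste("patient", p))
    }
  }
})

test_that("episodes of one patient never overlap and are numbered 1..k", {
  co <- simulate_cohort(sim_config(n_patients = 400, seed = 9))
  ep <- build_episodes(as_clinical_events(co$tables))
  ep <- ep[order(ep$patient_id, ep$start_date), ]
  by_pat <- split(ep, ep$patient_id)
  for (d in by_pat) {
    expect_equal(d$episode_number, seq_len(nrow(d)))
    if (nrow(d) > 1)
      expect_true(all(d$start_date[-1] > d$end_date[-nrow(d)]))
  }
})

test_that("exclusion rules drop episodes with machine-readable reasons", {
  dem <- data.frame(patient_id = 1:5,
                    birth_date = c(origin - round(17.9 * 365.25),  # age
                                   origin - 40 * 365,
                                   origin - 40 * 365,
                                   origin - 40 * 365,
                                   as.Date(NA)),                  # missing
                    residency_start = c(rep(origin - 3000, 3),
                                        origin - round(11 * 30.4), # 11 months
                                        origin - 3000),
                    residency_end = rep(origin + 2000, 5))
  ep <- do.call(rbind, lapply(1:5, function(p)
    mk_events(0, "diagnosis", "F32.0", patient_id = p)))
  built <- build_episodes(ep)
  dx <- data.frame(patient_id = 2L, date = origin - 500, icd10 = "F31.8",
                   care_setting = "psychiatric", locus = "outpatient")
  res <- apply_exclusions(built, dem, dx)
  lg <- res$log[order(res$log$patient_id), ]
  expect_equal(lg$patient_id, c(1L, 2L, 4L, 5L))
  expect_equal(lg$reason, c("age", "excluded_diagnosis", "residency",
                            "missing_demographics"))
  expect_equal(res$kept$patient_id, 3L)
  expect_gt(res$kept$age_at_start, 18)
})

test_that("a patient aged exactly 18 at start is kept", {
  dem <- data.frame(patient_id = 1L, birth_date = origin - ceiling(18 * 365.25),
                    residency_start = origin - 3000,
                    residency_end = origin + 2000)
  built <- build_episodes(mk_events(0, "diagnosis", "F32.0"))
  res <- apply_exclusions(built, dem, data.frame(patient_id = integer(0),
                                                 date = as.Date(character(0)),
                                                 icd10 = character(0)))
  expect_equal(nrow(res$kept), 1L)
  expect_equal(nrow(res$log), 0L)
})
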