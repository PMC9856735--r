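#' Rule set for treatment-trial identification
#'
#' Thresholds and code sets for the TRD case definition: a drug trial must
#' start within the episode, more than `gap_days` after the previous trial
#' initiation, and cover at least `min_duration_days`; dispensations of one
#' drug separated by at most `grace_days` beyond the supplied days merge into
#' one exposure; quetiapine counts as an add-on only above
#' `quetiapine_min_dose_mg` mg/day; consecutive ECT/rTMS sessions at most
#' `ect_course_gap_days` apart collapse into one course (one trial), and
#' gap/duration criteria do not apply to ECT/rTMS.
#'
#' @param gap_days minimum days (strict) between successive trial initiations.
#' @param min_duration_days minimum exposure duration of a drug trial.
#' @param grace_days grace period when merging dispensations into exposures.
#' @param addon_codes ATC codes of qualifying add-on medications.
#' @param quetiapine_code ATC code carrying the dose floor.
#' @param quetiapine_min_dose_mg dose floor (strictly greater qualifies).
#' @param ect_course_gap_days max gap between sessions of one ECT/rTMS course.
#' @param prior_initiation `"accepted"` measures the inter-trial gap from the
#'   previous accepted trial (default); `"any"` from the latest earlier
#'   candidate initiation, accepted or not.
#' @return list of class `trd_rules`.
#' @export
trd_rules <- function(gap_days = 28L, min_duration_days = 28L, grace_days = 30L,
                      addon_codes = default_episode_codes()$addon_codes,
                      quetiapine_code = "N05AH04",
                      quetiapine_min_dose_mg = 100,
                      ect_course_gap_days = 14L,
                      prior_initiation = c("accepted", "any")) {
  for (f in c("gap_days", "min_duration_days", "grace_days",
              "ect_course_gap_days", "quetiapine_min_dose_mg")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop_field(f, "must be a single positive number")
  }
  structure(list(gap_days = gap_days, min_duration_days = min_duration_days,
                 grace_days = grace_days, addon_codes = addon_codes,
                 quetiapine_code = quetiapine_code,
                 quetiapine_min_dose_mg = quetiapine_min_dose_mg,
                 ect_course_gap_days = ect_course_gap_days,
                 prior_initiation = match.arg(prior_initiation)),
            class = "trd_rules")
}

#' Estimate drug exposure intervals from dispensations
#'
#' Each dispensation covers `supply_days` days from its date. Consecutive
#' dispensations of the same drug for the same patient whose gap between the
#' end of covered time and the next fill is at most `grace_days` merge into
#' one exposure interval; the interval ends on the last covered day.
#'
#' @param dispensations table with `patient_id`, `date`, `atc`, `supply_days`
#'   and optionally `daily_dose_mg`.
#' @param grace_days allowed coverage gap before an exposure is split.
#' @return data.table of intervals: `patient_id`, `treatment_key`,
#'   `start_date`, `end_date`, `duration_days`, `n_fills`, `init_dose_mg`.
#' @export
estimate_exposure <- function(dispensations, grace_days = 30L) {
  proto <- c(patient_id = "integer", treatment_key = "character",
             start_date = "Date", end_date = "Date", duration_days = "numeric",
             n_fills = "integer", init_dose_mg = "numeric")
  if (is.null(dispensations) || !nrow(dispensations)) return(empty_table(proto))
  require_columns(dispensations, c("patient_id", "date", "atc", "supply_days"),
                  "dispensations")
  d <- data.table::as.data.table(dispensations)
  if (any(is.na(d$supply_days)) || any(d$supply_days < 1))
    stop_field("supply_days", "every dispensation needs supply_days >= 1")
  d[, date := as_day(date)]
  if (!"daily_dose_mg" %in% names(d)) d[, daily_dose_mg := NA_real_]
  data.table::setorder(d, patient_id, atc, date, -supply_days, na.last = TRUE)
  d[, cover_end := date + as.integer(supply_days) - 1L]
  # running coverage end within patient+drug; a new interval starts when the
  # fill date exceeds previous coverage + grace
  d[, run_end := as.Date(cummax(as.integer(cover_end)), origin = "1970-01-01"),
    by = .(patient_id, atc)]
  d[, new_iv := date > data.table::shift(run_end) + grace_days, by = .(patient_id, atc)]
  d[is.na(new_iv), new_iv := TRUE]
  d[, iv := cumsum(new_iv), by = .(patient_id, atc)]
  out <- d[, .(start_date = min(date), end_date = max(cover_end),
               n_fills = .N, init_dose_mg = daily_dose_mg[1L]),
           by = .(patient_id, treatment_key = atc, iv)]
  out[, iv := NULL]
  out[, duration_days := as.numeric(end_date - start_date) + 1]
  data.table::setorder(out, patient_id, treatment_key, start_date)
  data.table::setcolorder(out, names(proto))
  out[]
}

# collapse ECT/rTMS sessions into courses: one row per course at its first date
collapse_procedure_courses <- function(proc, gap) {
  data.table::setorder(proc, patient_id, procedure, date)
  proc[, new_course := c(TRUE, diff(as.integer(date)) > gap),
       by = .(patient_id, procedure)]
  proc[, course := cumsum(new_course), by = .(patient_id, procedure)]
  proc[, .(date = min(date)), by = .(patient_id, procedure, course)][, course := NULL][]
}

#' Identify treatment trials within MDD episodes
#'
#' Applies the trial rules to every episode at once: a drug exposure is a
#' candidate iff its interval starts within the episode (exposures initiated
#' before the episode start never count), lasts at least
#' `rules$min_duration_days`, and (for quetiapine) exceeds the dose floor; a
#' candidate is accepted iff its initiation is strictly more than
#' `rules$gap_days` after the previous accepted initiation. ECT/rTMS courses
#' within the episode are always accepted, exempt from gap and duration
#' criteria. Same-day candidates are ordered procedures first, then longer
#' exposure, then lexicographic ATC code, making acceptance deterministic.
#'
#' @param episodes episode table ([build_episodes()]).
#' @param exposures exposure intervals ([estimate_exposure()]).
#' @param procedures optional table `patient_id`, `date`, `procedure`
#'   (only `ECT`/`rTMS` rows are considered).
#' @param rules a [trd_rules()] object.
#' @return data.table of trials: `episode_id`, `patient_id`, `trial_index`,
#'   `treatment_key`, `treatment_class`, `initiation_date`, `is_procedure`,
#'   `duration_days`.
#' @export
identify_trials <- function(episodes, exposures, procedures = NULL,
                            rules = trd_rules()) {
  stopifnot(inherits(rules, "trd_rules"))
  proto <- c(episode_id = "integer", patient_id = "integer",
             trial_index = "integer", treatment_key = "character",
             treatment_class = "character", initiation_date = "Date",
             is_procedure = "logical", duration_days = "numeric")
  ep <- data.table::as.data.table(episodes)
  if (!nrow(ep)) return(empty_table(proto))
  require_columns(ep, c("patient_id", "start_date", "end_date"), "episodes")
  if (!"episode_id" %in% names(ep)) ep[, episode_id := seq_len(.N)]

  cand <- list()
  ex <- data.table::as.data.table(exposures)
  if (nrow(ex)) {
    is_ad <- code_matches(ex$treatment_key, "N06A")
    is_addon <- ex$treatment_key %in% rules$addon_codes
    ex <- ex[is_ad | is_addon]
    # dose floor on the initiating dispensation
    ex <- ex[!(treatment_key == rules$quetiapine_code &
                 !(ifelse(is.na(init_dose_mg), 0, init_dose_mg) >
                     rules$quetiapine_min_dose_mg))]
    ex <- ex[duration_days >= rules$min_duration_days]
    if (nrow(ex)) {
      hit <- ex[ep, on = .(patient_id, start_date >= start_date,
                           start_date <= end_date),
                .(episode_id = i.episode_id, patient_id,
                  treatment_key = x.treatment_key,
                  initiation_date = x.start_date,
                  duration_days = x.duration_days, is_procedure = FALSE),
                nomatch = NULL]
      cand$drug <- hit
    }
  }
  if (!is.null(procedures) && nrow(procedures)) {
    pr <- data.table::as.data.table(procedures)[procedure %in% c("ECT", "rTMS")]
    if (nrow(pr)) {
      courses <- collapse_procedure_courses(pr, rules$ect_course_gap_days)
      hit <- courses[ep, on = .(patient_id, date >= start_date,
                                date <= end_date),
                     .(episode_id = i.episode_id, patient_id,
                       treatment_key = x.procedure, initiation_date = x.date,
                       duration_days = NA_real_, is_procedure = TRUE),
                     nomatch = NULL]
      cand$proc <- hit
    }
  }
  cand <- data.table::rbindlist(cand, use.names = TRUE)
  if (!nrow(cand)) return(empty_table(proto))

  # deterministic candidate order within episode
  data.table::setorder(cand, episode_id, initiation_date, -is_procedure,
                       -duration_days, treatment_key, na.last = TRUE)
  cand[, acc := greedy_accept(as.integer(initiation_date), is_procedure,
                              rules$gap_days, rules$prior_initiation == "any"),
       by = episode_id]
  out <- cand[acc == TRUE]
  out[, acc := NULL]
  out[, trial_index := seq_len(.N), by = episode_id]
  cmap <- default_treatment_classes()
  out[, treatment_class := cmap$class[match(treatment_key, cmap$code)]]
  out[is.na(treatment_class), treatment_class := "other_AD"]
  data.table::setcolorder(out, names(proto))
  out[]
}

# sequential acceptance walk over one episode's candidates (already sorted)
greedy_accept <- function(init, is_proc, gap, from_any) {
  n <- length(init)
  acc <- logical(n)
  last <- -Inf   # initiation of previous accepted trial
  ref <- -Inf    # latest earlier candidate initiation (for prior_initiation = "any")
  for (i in seq_len(n)) {
    prev <- if (from_any) max(last, ref) else last
    if (is_proc[i] || prev == -Inf || init[i] - prev > gap) {
      acc[i] <- TRUE
      last <- max(last, init[i])
    }
    ref <- max(ref, init[i])
  }
  acc
}

#' Classify treatment-resistant depression per episode
#'
#' An episode is TRD iff it contains three or more valid treatment trials;
#' the TRD index date is the initiation date of the third trial.
#'
#' @param trials output of [identify_trials()].
#' @param episodes episode table; every episode gets a row in the result
#'   (episodes without trials have `n_trials = 0`).
#' @return data.table: episode columns plus `n_trials`, `is_trd`,
#'   `index_date`, `time_to_trd_days`.
#' @export
classify_trd <- function(trials, episodes) {
  ep <- data.table::as.data.table(episodes)
  if (!"episode_id" %in% names(ep)) ep[, episode_id := seq_len(.N)]
  out <- data.table::copy(ep)
  tr <- data.table::as.data.table(trials)
  if (nrow(tr)) {
    agg <- tr[, .(n_trials = .N,
                  index_date = if (.N >= 3L) initiation_date[3L] else as.Date(NA)),
              by = episode_id]
    out[agg, on = "episode_id", `:=`(n_trials = i.n_trials,
                                     index_date = i.index_date)]
  }
  if (!"n_trials" %in% names(out)) out[, n_trials := NA_integer_]
  out[is.na(n_trials), n_trials := 0L]
  if (!"index_date" %in% names(out)) out[, index_date := as.Date(NA)]
  out[, is_trd := n_trials >= 3L]
  out[, time_to_trd_days := as.numeric(index_date - start_date)]
  out[]
}
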