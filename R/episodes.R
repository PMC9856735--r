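#' Flatten registry tables into one clinical event stream
#'
#' Combines the per-domain registry tables (diagnoses, dispensations,
#' procedures, sick leave, ratings) into a single event table with one row per
#' dated clinical event, the representation consumed by [build_episodes()].
#'
#' @param tables named list with any of `diagnoses`, `dispensations`,
#'   `procedures`, `sick_leave`, `ratings` (as produced by
#'   [simulate_cohort()] or read from delimited files with the same schema).
#' @return data.table with columns `patient_id`, `date`, `kind`, `code`,
#'   `care_setting`, `locus`, `supply_days`, `daily_dose_mg`, `score`.
#' @export
as_clinical_events <- function(tables) {
  pieces <- list()
  blank <- function(n) rep(NA_character_, n)
  if (!is.null(tables$diagnoses) && nrow(tables$diagnoses)) {
    d <- tables$diagnoses
    require_columns(d, c("patient_id", "date", "icd10"), "diagnoses")
    pieces$dx <- data.table::data.table(
      patient_id = d$patient_id, date = as_day(d$date), kind = "diagnosis",
      code = d$icd10,
      care_setting = if ("care_setting" %in% names(d)) d$care_setting else blank(nrow(d)),
      locus = if ("locus" %in% names(d)) d$locus else blank(nrow(d)),
      supply_days = NA_real_, daily_dose_mg = NA_real_, score = NA_real_)
  }
  if (!is.null(tables$dispensations) && nrow(tables$dispensations)) {
    d <- tables$dispensations
    require_columns(d, c("patient_id", "date", "atc", "supply_days"), "dispensations")
    pieces$rx <- data.table::data.table(
      patient_id = d$patient_id, date = as_day(d$date), kind = "dispensation",
      code = d$atc, care_setting = blank(nrow(d)), locus = blank(nrow(d)),
      supply_days = as.numeric(d$supply_days),
      daily_dose_mg = if ("daily_dose_mg" %in% names(d)) as.numeric(d$daily_dose_mg) else rep(NA_real_, nrow(d)),
      score = NA_real_)
  }
  if (!is.null(tables$procedures) && nrow(tables$procedures)) {
    d <- tables$procedures
    require_columns(d, c("patient_id", "date", "procedure"), "procedures")
    pieces$pr <- data.table::data.table(
      patient_id = d$patient_id, date = as_day(d$date), kind = "procedure",
      code = d$procedure, care_setting = blank(nrow(d)), locus = blank(nrow(d)),
      supply_days = NA_real_, daily_dose_mg = NA_real_, score = NA_real_)
  }
  if (!is.null(tables$sick_leave) && nrow(tables$sick_leave)) {
    d <- tables$sick_leave
    require_columns(d, c("patient_id", "start_date"), "sick_leave")
    pieces$sl <- data.table::data.table(
      patient_id = d$patient_id, date = as_day(d$start_date), kind = "sick_leave",
      code = NA_character_, care_setting = blank(nrow(d)), locus = blank(nrow(d)),
      supply_days = NA_real_, daily_dose_mg = NA_real_, score = NA_real_)
  }
  if (!is.null(tables$ratings) && nrow(tables$ratings)) {
    d <- tables$ratings
    require_columns(d, c("patient_id", "date", "score"), "ratings")
    pieces$rt <- data.table::data.table(
      patient_id = d$patient_id, date = as_day(d$date), kind = "rating",
      code = "MADRS-S", care_setting = blank(nrow(d)), locus = blank(nrow(d)),
      supply_days = NA_real_, daily_dose_mg = NA_real_, score = as.numeric(d$score))
  }
  if (!length(pieces)) {
    return(empty_table(c(patient_id = "integer", date = "Date", kind = "character",
                         code = "character", care_setting = "character",
                         locus = "character", supply_days = "numeric",
                         daily_dose_mg = "numeric", score = "numeric")))
  }
  out <- data.table::rbindlist(pieces, use.names = TRUE)
  data.table::setorder(out, patient_id, date)
  out[]
}

#' Construct MDD episodes from a clinical event stream
#'
#' An episode opens at an F32/F33 diagnosis that is not covered by an already
#' open episode, accretes depression-related events (diagnoses,
#' antidepressant and add-on dispensations, ECT/rTMS/psychotherapy contacts)
#' while successive inter-event gaps are shorter than `gap_days`, and closes
#' at the last accreted event once a quiet interval of at least `gap_days`
#' follows. A later F32/F33 diagnosis after such a quiet interval opens a new
#' episode. All date arithmetic is in whole days on closed intervals.
#'
#' @param events clinical event table ([as_clinical_events()]) or a named list
#'   of registry tables, which is flattened first.
#' @param gap_days quiet-gap threshold in days closing an episode (default 365).
#' @param codes depression-related code sets, see [default_episode_codes()].
#' @param demographics optional demographics table (`patient_id`,
#'   `birth_date`); when supplied, `age_at_start` is filled in.
#' @return data.table of episodes: `patient_id`, `episode_id`,
#'   `episode_number`, `start_date`, `end_date`, `care_setting_at_start`,
#'   `age_at_start`.
#' @export
build_episodes <- function(events, gap_days = 365L,
                           codes = default_episode_codes(),
                           demographics = NULL) {
  if (!is.numeric(gap_days) || length(gap_days) != 1L || gap_days < 1)
    stop_field("gap_days", "must be a single count >= 1")
  if (is.list(events) && !is.data.frame(events)) events <- as_clinical_events(events)
  require_columns(events, c("patient_id", "date", "kind", "code"), "events")
  if (anyNA(events$patient_id) || anyNA(events$date))
    stop("events contain missing patient_id or date", call. = FALSE)

  ev <- data.table::as.data.table(events)
  ev[, date := as_day(date)]

  is_dx <- ev$kind == "diagnosis" & code_matches(ev$code, codes$diagnosis_prefixes)
  is_rx <- ev$kind == "dispensation" &
    (code_matches(ev$code, codes$antidepressant_prefixes) |
       ev$code %in% codes$addon_codes)
  is_pr <- ev$kind == "procedure" & ev$code %in% codes$procedures
  dep <- ev[is_dx | is_rx | is_pr]
  dep[, opens := kind == "diagnosis" & code_matches(code, codes$diagnosis_prefixes)]
  if (!nrow(dep)) {
    out <- empty_table(c(patient_id = "integer", episode_id = "integer",
                         episode_number = "integer", start_date = "Date",
                         end_date = "Date", care_setting_at_start = "character",
                         age_at_start = "numeric"))
    return(out)
  }
  data.table::setorder(dep, patient_id, date)

  # chain events into runs: a run breaks when the gap to the previous
  # depression-related event reaches gap_days
  dep[, gap := c(Inf, diff(as.integer(date))), by = patient_id]
  dep[, run := cumsum(gap >= gap_days), by = patient_id]

  # an episode exists for every run containing at least one opening diagnosis;
  # it starts at the run's first opening diagnosis and ends at the run's last
  # event on or after that start
  runs <- dep[, {
    if (any(opens)) {
      s <- min(date[opens])
      open_rows <- which(opens & date == s)
      cs <- care_setting[open_rows]
      cs <- if (any(cs == "psychiatric", na.rm = TRUE)) "psychiatric" else cs[1L]
      list(start_date = s, end_date = max(date[date >= s]),
           care_setting_at_start = cs)
    }
  }, by = .(patient_id, run)]
  if (!nrow(runs)) {
    return(empty_table(c(patient_id = "integer", episode_id = "integer",
                         episode_number = "integer", start_date = "Date",
                         end_date = "Date", care_setting_at_start = "character",
                         age_at_start = "numeric")))
  }
  runs[, run := NULL]
  data.table::setorder(runs, patient_id, start_date)
  runs[, episode_number := seq_len(.N), by = patient_id]
  runs[, episode_id := seq_len(.N)]
  runs[, age_at_start := NA_real_]
  if (!is.null(demographics)) {
    require_columns(demographics, c("patient_id", "birth_date"), "demographics")
    dem <- data.table::as.data.table(demographics)[, .(patient_id, birth_date = as_day(birth_date))]
    runs[dem, on = "patient_id",
         age_at_start := as.numeric(start_date - i.birth_date) / 365.25]
  }
  data.table::setcolorder(runs, c("patient_id", "episode_id", "episode_number",
                                  "start_date", "end_date",
                                  "care_setting_at_start", "age_at_start"))
  runs[]
}

#' Apply study inclusion/exclusion rules to built episodes
#'
#' Keeps episodes where the patient was at least 18 years old at episode
#' start, had more than `lookback_months` of continuous residency before the
#' start, and has no record (at any time) of an exclusion diagnosis
#' (psychosis, bipolar disorder, manic episode, dementia). Every dropped
#' episode is logged with one machine-readable reason.
#'
#' @param episodes output of [build_episodes()].
#' @param demographics table with `patient_id`, `birth_date`.
#' @param diagnoses diagnosis table (`patient_id`, `date`, `icd10`) searched
#'   for exclusion codes.
#' @param residency table with `patient_id`, `start_date`, `end_date` of
#'   residency intervals; if `NULL`, residency columns on `demographics`
#'   (`residency_start`, `residency_end`) are used.
#' @param lookback_months required continuous pre-start residency, months.
#' @param exclusion_codes ICD-10 prefixes, see [default_exclusion_codes()].
#' @param min_age minimum age in years at episode start.
#' @return list with `kept` (episode table, age filled in) and `log`
#'   (data.table `patient_id`, `episode_id`, `reason`).
#' @export
apply_exclusions <- function(episodes, demographics, diagnoses,
                             residency = NULL, lookback_months = 12,
                             exclusion_codes = default_exclusion_codes(),
                             min_age = 18) {
  ep <- data.table::as.data.table(episodes)
  if (!nrow(ep)) return(list(kept = ep, log = data.table::data.table(
    patient_id = integer(0), episode_id = integer(0), reason = character(0))))
  dem <- data.table::as.data.table(demographics)
  require_columns(dem, c("patient_id", "birth_date"), "demographics")
  if (is.null(residency)) {
    require_columns(dem, c("residency_start", "residency_end"), "demographics")
    residency <- dem[, .(patient_id, start_date = residency_start,
                         end_date = residency_end)]
  }
  res <- data.table::as.data.table(residency)
  require_columns(res, c("patient_id", "start_date", "end_date"), "residency")

  ep <- data.table::copy(ep)
  ep[dem, on = "patient_id", birth_date := as_day(i.birth_date)]
  ep[, age_at_start := as.numeric(start_date - birth_date) / 365.25]

  lookback_days <- round(lookback_months * 365.25 / 12)
  # residency interval containing the episode start, and its pre-start length
  res[, `:=`(start_date = as_day(start_date), end_date = as_day(end_date))]
  cover <- res[ep, on = .(patient_id, start_date <= start_date,
                          end_date >= start_date),
               .(episode_id = i.episode_id,
                 pre_days = as.numeric(i.start_date - x.start_date))]
  cover <- cover[, .(pre_days = suppressWarnings(max(pre_days))), by = episode_id]
  ep[cover, on = "episode_id", pre_days := i.pre_days]

  excl_pat <- unique(diagnoses$patient_id[
    code_matches(diagnoses$icd10, exclusion_codes)])

  reason <- rep(NA_character_, nrow(ep))
  reason[is.na(ep$birth_date)] <- "missing_demographics"
  sel <- is.na(reason) & ep$patient_id %in% excl_pat
  reason[sel] <- "excluded_diagnosis"
  sel <- is.na(reason) & ep$age_at_start < min_age
  reason[sel] <- "age"
  sel <- is.na(reason) & (is.na(ep$pre_days) | ep$pre_days <= lookback_days)
  reason[sel] <- "residency"

  log <- ep[!is.na(reason), .(patient_id, episode_id)]
  log[, reason := reason[!is.na(reason)]]
  kept <- ep[is.na(reason)]
  kept[, c("birth_date", "pre_days") := NULL]
  list(kept = kept[], log = log[])
}
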