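#' Configuration for the synthetic registry generator
#'
#' Bundles and validates all generator parameters. Defaults emulate the
#' study conditions of the registry analysis: an 11% TRD-track probability
#' among treated, fully eligible episodes; log-normal inter-initiation gaps
#' with medians near 165 and 197 days (first-trial delay median 8 days);
#' episodes separated by quiet gaps longer than one year; baseline all-cause
#' mortality of 8.7 per 1000 person-years with a multiplicative hazard on
#' planted-TRD person-time; and 95% missing-at-random deletion of MADRS-S
#' ratings.
#'
#' @param n_patients number of patients to generate.
#' @param date_start,date_end calendar bounds of the registry extract.
#' @param episode_start_min,episode_start_max window in which episodes start.
#' @param p_trd_track probability that a treated, fully eligible episode is
#'   generated on a >= 3-trial (TRD) trajectory; the covariate model's
#'   intercept is calibrated so this is the mean planting rate.
#' @param first_trial_meanlog,first_trial_sdlog log-normal parameters of the
#'   delay from episode start to first treatment initiation (days).
#' @param switch_meanlog,switch_sdlog length-2 log-normal parameters of the
#'   trial 1-to-2 and 2-to-3 initiation gaps (days); draws are floored at 29
#'   days so planted trials always satisfy the >28-day gap rule.
#' @param episode_gap_days quiet gap separating generated episodes (> 365).
#' @param baseline_mortality_rate all-cause deaths per 1000 person-years.
#' @param trd_mortality_hr hazard ratio applied to person-time after the
#'   first planted TRD index date.
#' @param selfharm_rate_non_trd,selfharm_rate_trd intentional self-harm
#'   events per 1000 person-years by planted track.
#' @param madrs_missing_rate fraction of MADRS-S ratings deleted missing at
#'   random (logistic in care setting and prior visit count).
#' @param madrs_effect log-odds of the TRD track per standard deviation of
#'   the latent MADRS-S score.
#' @param track_coefs log-odds contributions of the remaining baseline
#'   covariates to the TRD track.
#' @param comorbidity_rates named probabilities for pre-start comorbidity
#'   flags (`anxiety`, `sleep_disorder`) and for extra diagnosis onsets
#'   around the index date (`onset_trd`, `onset_non_trd`).
#' @param p_treated probability an episode has antidepressant treatment.
#' @param seed integer RNG seed; identical seed and config reproduce
#'   byte-identical tables.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000L,
                       date_start = "2010-01-01", date_end = "2018-12-31",
                       episode_start_min = "2012-01-01",
                       episode_start_max = "2017-12-31",
                       p_trd_track = 0.11,
                       first_trial_meanlog = log(8), first_trial_sdlog = 1.5,
                       switch_meanlog = c(log(165), log(197)),
                       switch_sdlog = c(1.20, 1.15),
                       episode_gap_days = 400,
                       baseline_mortality_rate = 8.7,
                       trd_mortality_hr = 1.23,
                       selfharm_rate_non_trd = 2.5,
                       selfharm_rate_trd = 6,
                       madrs_missing_rate = 0.95,
                       madrs_effect = 0.9,
                       track_coefs = c(care_psychiatric = 0.5,
                                       log_visits = 0.25, sleep = 0.35,
                                       anxiety = 0.35, male = 0.15),
                       comorbidity_rates = c(anxiety = 0.35,
                                             sleep_disorder = 0.20,
                                             onset_trd = 0.35,
                                             onset_non_trd = 0.12),
                       p_treated = 0.73,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              date_start = as_day(date_start), date_end = as_day(date_end),
              episode_start_min = as_day(episode_start_min),
              episode_start_max = as_day(episode_start_max),
              p_trd_track = p_trd_track,
              first_trial_meanlog = first_trial_meanlog,
              first_trial_sdlog = first_trial_sdlog,
              switch_meanlog = switch_meanlog, switch_sdlog = switch_sdlog,
              episode_gap_days = episode_gap_days,
              baseline_mortality_rate = baseline_mortality_rate,
              trd_mortality_hr = trd_mortality_hr,
              selfharm_rate_non_trd = selfharm_rate_non_trd,
              selfharm_rate_trd = selfharm_rate_trd,
              madrs_missing_rate = madrs_missing_rate,
              madrs_effect = madrs_effect,
              track_coefs = track_coefs,
              comorbidity_rates = comorbidity_rates,
              p_treated = p_treated, seed = as.integer(seed))
  if (is.na(cfg$n_patients) || cfg$n_patients < 0)
    stop_field("n_patients", "must be a non-negative count")
  for (f in c("p_trd_track", "madrs_missing_rate", "p_treated")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must be a probability in [0, 1]")
  }
  for (f in c("baseline_mortality_rate", "trd_mortality_hr",
              "selfharm_rate_non_trd", "selfharm_rate_trd")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_field(f, "must be a non-negative rate")
  }
  if (any(cfg$comorbidity_rates < 0) || any(cfg$comorbidity_rates > 1))
    stop_field("comorbidity_rates", "must be probabilities in [0, 1]")
  if (!is.numeric(cfg$episode_gap_days) || cfg$episode_gap_days <= 365)
    stop_field("episode_gap_days", "must exceed 365 days")
  if (length(cfg$switch_meanlog) != 2L || length(cfg$switch_sdlog) != 2L)
    stop_field("switch_meanlog", "switch distribution needs 2 parameters")
  if (is.na(cfg$seed)) stop_field("seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

# solve the intercept a such that mean(plogis(a + eta)) = target
calibrate_intercept <- function(eta, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - target,
                 lower = -30, upper = 30, tol = 1e-10)$root
}

# drug pools used for trial assignment (N06AA02 is reserved for pre-episode
# noise dispensations and never assigned to a trial)
sim_class_pools <- function() {
  list(SSRI = c("N06AB03", "N06AB04", "N06AB05", "N06AB06", "N06AB10"),
       SNRI = c("N06AX16", "N06AX21"),
       NaSSA = "N06AX11",
       NDRI = "N06AX12",
       TCA = c("N06AA04", "N06AA09", "N06AA10"),
       other_AD = c("N06AX03", "N06AX05", "N06AG02"),
       agomelatine = "N06AX22",
       vortioxetine = "N06AX26",
       add_on = c("N05AX12", "N05AN01", "N05AH03", "N05AH04", "N05AX08"),
       ECT_rTMS = c("ECT", "rTMS"))
}

# treatment-class probabilities by trial position (rows: positions 1..4)
sim_position_probs <- function() {
  cls <- c("SSRI", "SNRI", "NaSSA", "NDRI", "TCA", "other_AD", "agomelatine",
           "vortioxetine", "add_on", "ECT_rTMS")
  m <- rbind(
    c(0.60, 0.12, 0.09, 0.05, 0.05, 0.04, 0.02, 0.03, 0.00, 0.00),
    c(0.30, 0.20, 0.15, 0.10, 0.07, 0.05, 0.04, 0.06, 0.03, 0.00),
    c(0.18, 0.15, 0.14, 0.13, 0.06, 0.05, 0.04, 0.07, 0.12, 0.06),
    c(0.18, 0.15, 0.14, 0.13, 0.06, 0.05, 0.04, 0.07, 0.12, 0.06))
  colnames(m) <- cls
  m
}

cohort_table_protos <- function() {
  list(
    demographics = c(patient_id = "integer", birth_date = "Date",
                     sex = "character", ses = "integer",
                     residency_start = "Date", residency_end = "Date"),
    diagnoses = c(patient_id = "integer", date = "Date", icd10 = "character",
                  care_setting = "character", locus = "character",
                  discharge_date = "Date"),
    dispensations = c(patient_id = "integer", date = "Date",
                      atc = "character", supply_days = "integer",
                      daily_dose_mg = "numeric"),
    procedures = c(patient_id = "integer", date = "Date",
                   procedure = "character"),
    sick_leave = c(patient_id = "integer", start_date = "Date",
                   end_date = "Date"),
    ratings = c(patient_id = "integer", date = "Date", score = "numeric"),
    vital_status = c(patient_id = "integer", death_date = "Date")
  )
}

empty_cohort_tables <- function() lapply(cohort_table_protos(), empty_table)

#' Generate a synthetic registry cohort with planted ground truth
#'
#' Emits the seven registry tables (demographics, diagnoses, dispensations,
#' procedures, sick leave, MADRS-S ratings, vital status) for a cohort of
#' depressed patients, together with the generative ground truth: per-episode
#' planted TRD labels and index dates, per-patient mortality hazard
#' multipliers, and the true covariate coefficients of the TRD track model.
#' Planted-TRD episodes contain, by construction, three or more treatment
#' initiations satisfying the trial rules of [identify_trials()], so the
#' rule-based classifier recovers the planted labels exactly. Death, end of
#' residency, and the end of the study window truncate all later events;
#' planted labels whose third trial is truncated away are demoted, keeping
#' labels and emitted events consistent.
#'
#' @param config a [sim_config()] object.
#' @return object of class `trd_cohort`: list with `tables` (seven
#'   data.tables), `ground_truth` (`episodes`, `patients`,
#'   `true_coefficients`) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  gt_ep_proto <- c(patient_id = "integer", episode_number = "integer",
                   start_date = "Date", end_date = "Date", treated = "logical",
                   planted_track = "logical",
                   planted_trd = "logical", trd_index_date = "Date",
                   time_to_trd_days = "numeric", n_trials = "integer",
                   severity = "numeric", madrs_true = "numeric",
                   care_psychiatric = "logical", visits_12m = "integer",
                   anxiety_flag = "logical", sleep_flag = "logical",
                   eligible = "logical")
  true_coefs <- c(madrs = config$madrs_effect, config$track_coefs)
  if (n == 0L) {
    return(structure(list(
      tables = empty_cohort_tables(),
      ground_truth = list(
        episodes = empty_table(gt_ep_proto),
        patients = empty_table(c(patient_id = "integer",
                                 hazard_multiplier = "numeric",
                                 death_date = "Date", cutoff = "Date")),
        true_coefficients = true_coefs),
      config = config), class = "trd_cohort"))
  }

  ## ---- patients -----------------------------------------------------------
  pat <- data.table::data.table(patient_id = seq_len(n))
  pat[, sex := ifelse(stats::runif(n) < 0.635, "F", "M")]
  pat[, ses := sample.int(5L, n, replace = TRUE,
                          prob = c(0.10, 0.20, 0.35, 0.25, 0.10))]
  pat[, n_ep := sample(1:3, n, replace = TRUE, prob = c(0.72, 0.20, 0.08))]
  pat[, minor := stats::runif(n) < 0.01]
  pat[, excl_dx := stats::runif(n) < 0.025]
  pat[, late_res := stats::runif(n) < 0.03]
  pat[, emigrant := stats::runif(n) < 0.03]
  pat[, age1 := pmin(85, pmax(19, stats::rnorm(n, 44, 14)))]
  if (any(pat$minor)) pat[minor == TRUE, age1 := stats::runif(.N, 16, 17.9)]

  ## ---- episode-level covariates and TRD track -----------------------------
  ep <- pat[rep(seq_len(n), n_ep),
            .(patient_id, sex, minor, excl_dx, late_res, emigrant, age1)]
  m <- nrow(ep)
  ep[, severity := stats::rnorm(m)]
  ep[, madrs_true := pmin(54, pmax(0, round(24 + 9 * severity +
                                              stats::rnorm(m, 0, 3))))]
  ep[, care_psychiatric := stats::runif(m) < stats::plogis(-0.95 + 0.9 * severity)]
  ep[, visits_12m := stats::rpois(m, exp(0.9 + 0.35 * severity))]
  ep[, anxiety_flag := stats::runif(m) < stats::plogis(-0.5 + 0.6 * severity)]
  ep[, sleep_flag := stats::runif(m) < stats::plogis(-1.3 + 0.6 * severity)]
  ep[, eligible := !minor & !excl_dx & !late_res & !emigrant]
  ep[, treated := stats::runif(m) < config$p_treated]

  b <- config$track_coefs
  lv <- log1p(ep$visits_12m)
  eta <- config$madrs_effect * (ep$madrs_true - 24) / 9 +
    b[["care_psychiatric"]] * ep$care_psychiatric +
    b[["log_visits"]] * (lv - mean(lv)) +
    b[["sleep"]] * ep$sleep_flag + b[["anxiety"]] * ep$anxiety_flag +
    b[["male"]] * (ep$sex == "M")
  track_ok <- ep$eligible & ep$treated
  ep[, planted := FALSE]
  if (config$p_trd_track > 0 && any(track_ok)) {
    a <- calibrate_intercept(eta[track_ok], config$p_trd_track)
    ep[, planted := track_ok & stats::runif(m) < stats::plogis(a + eta)]
  }

  ## trial counts and offsets (days from episode start)
  ep[, n_trials_gen := 0L]
  ep[treated == TRUE & planted == FALSE,
     n_trials_gen := 1L + (stats::runif(.N) < 0.35)]
  ep[planted == TRUE, n_trials_gen := 3L + (stats::runif(.N) < 0.2)]
  ep[, o1 := NA_real_]
  ep[treated == TRUE,
     o1 := round(stats::rlnorm(.N, config$first_trial_meanlog,
                               config$first_trial_sdlog))]
  ep[, o2 := o1 + pmax(29, round(stats::rlnorm(m, config$switch_meanlog[1],
                                               config$switch_sdlog[1])))]
  ep[, o3 := o2 + pmax(29, round(stats::rlnorm(m, config$switch_meanlog[2],
                                               config$switch_sdlog[2])))]
  ep[, o4 := o3 + pmax(29, round(stats::rlnorm(m, config$switch_meanlog[2],
                                               config$switch_sdlog[2])))]
  ep[, o_last := data.table::fcase(n_trials_gen == 0L, NA_real_,
                                   n_trials_gen == 1L, o1,
                                   n_trials_gen == 2L, o2,
                                   n_trials_gen == 3L, o3,
                                   n_trials_gen == 4L, o4)]

  ## target span; follow-up visits keep the episode open over the whole span
  ep[, span := round(stats::rlnorm(m, log(90), 0.9)) + 7]
  ep[treated == TRUE & planted == FALSE,
     span := pmax(o_last + 100, round(stats::rlnorm(.N, log(550), 0.8)))]
  ep[planted == TRUE,
     span := o_last + round(stats::rlnorm(.N, log(180), 0.7)) + 30]

  ## cumulate start dates: start_{k+1} = start_k + span_k + quiet gap
  ep[, gap_after := config$episode_gap_days + round(stats::rexp(m, 1 / 200))]
  ep[, start_off := cumsum(data.table::shift(span + gap_after, fill = 0)),
     by = patient_id]
  first_start <- config$episode_start_min +
    floor(stats::runif(n) * as.numeric(config$episode_start_max -
                                         config$episode_start_min + 1))
  ep[, start_date := first_start[patient_id] + start_off]
  ep <- ep[start_date <= config$episode_start_max]
  m <- nrow(ep)

  ## ---- patient-level dates, mortality -------------------------------------
  pat <- pat[patient_id %in% ep$patient_id]
  first_ep <- ep[, .(first_start = min(start_date)), by = patient_id]
  pat[first_ep, on = "patient_id", first_start := i.first_start]
  pat[, birth_date := first_start - round(age1 * 365.25)]
  pat[, residency_start := config$date_start]
  if (any(pat$late_res))
    pat[late_res == TRUE,
        residency_start := first_start - round(stats::runif(.N, 30, 330))]
  pat[, residency_end := config$date_end]
  if (any(pat$emigrant))
    pat[emigrant == TRUE,
        residency_end := pmin(config$date_end,
                              first_start + round(stats::runif(.N, 200, 1500)))]

  pat[, t_idx := as.Date(NA)]
  if (any(ep$planted)) {
    idx <- ep[planted == TRUE, .(t_idx = min(start_date + o3)), by = patient_id]
    pat[idx, on = "patient_id", t_idx := i.t_idx]
  }
  rate0 <- config$baseline_mortality_rate / 1000 / 365.25
  pat[, hazard_multiplier := data.table::fifelse(is.na(t_idx), 1,
                                                 config$trd_mortality_hr)]
  entry <- pmax(pat$residency_start, config$date_start)
  if (rate0 > 0) {
    E <- stats::rexp(nrow(pat), rate0)       # draw on the baseline scale
    t1 <- as.numeric(pat$t_idx - entry)
    death_off <- ifelse(is.na(t1) | E <= t1, E,
                        t1 + (E - t1) / config$trd_mortality_hr)
    pat[, death_date := entry + round(death_off)]
    pat[death_date > config$date_end, death_date := as.Date(NA)]
  } else {
    pat[, death_date := as.Date(NA)]
  }
  pat[, cutoff := pmin(data.table::fifelse(is.na(death_date),
                                           config$date_end, death_date),
                       residency_end, config$date_end)]

  ep[pat, on = "patient_id", cutoff := i.cutoff]
  ep <- ep[start_date <= cutoff]           # episodes never observed
  m <- nrow(ep)
  ep[, episode_number := seq_len(.N), by = patient_id]
  ep[, eid := seq_len(m)]
  pat <- pat[patient_id %in% ep$patient_id]

  ## ---- trial table, drug codes, fills -------------------------------------
  pools <- sim_class_pools()
  probs <- sim_position_probs()
  has_tr <- ep$n_trials_gen > 0L
  tr <- NULL
  fills <- NULL
  if (any(has_tr)) {
    idxr <- rep(seq_len(m), ep$n_trials_gen)
    pos <- sequence(ep$n_trials_gen)
    omat <- as.matrix(ep[, .(o1, o2, o3, o4)])
    tr <- data.table::data.table(
      eid = ep$eid[idxr], patient_id = ep$patient_id[idxr],
      start_date = ep$start_date[idxr], span = ep$span[idxr],
      cutoff = ep$cutoff[idxr], pos = pos, off = omat[cbind(idxr, pos)])
    tr[, init_date := start_date + off]

    cls_names <- colnames(probs)
    u <- stats::runif(nrow(tr))
    cls_idx <- integer(nrow(tr))
    for (p in 1:4) {
      rows <- which(tr$pos == p)
      if (length(rows)) {
        cp <- cumsum(probs[p, ])
        cls_idx[rows] <- findInterval(u[rows], c(0, cp),
                                      rightmost.closed = TRUE)
      }
    }
    tr[, class := cls_names[cls_idx]]
    tr[, code := NA_character_]
    for (cl in unique(tr$class)) {
      rows <- which(tr$class == cl)
      pool <- pools[[cl]]
      pr <- if (cl == "ECT_rTMS") c(0.85, 0.15) else NULL
      tr$code[rows] <- pool[sample.int(length(pool), length(rows),
                                       replace = TRUE, prob = pr)]
    }
    ## resolve duplicate drug codes within an episode (keeps exposure
    ## intervals of distinct trials from merging)
    data.table::setorder(tr, eid, pos)
    dupflag <- rep(FALSE, nrow(tr))
    dd <- tr[, .(i = .I[duplicated(code) & class != "ECT_rTMS"]), by = eid]$i
    if (length(dd)) {
      all_drugs <- unique(unlist(pools[setdiff(names(pools), "ECT_rTMS")],
                                 use.names = FALSE))
      rows_by_eid <- split(seq_len(nrow(tr)), tr$eid)
      key <- match(tr$eid[dd], as.integer(names(rows_by_eid)))
      for (k in seq_along(dd)) {
        i <- dd[k]
        rows <- rows_by_eid[[key[k]]]
        cand <- c(pools[[tr$class[i]]], all_drugs)
        cand <- cand[!cand %in% tr$code[rows]]
        tr$code[i] <- cand[1L]
      }
    }

    ## dispensations: contiguous fills, clipped to the episode span
    drug <- tr[class != "ECT_rTMS"]
    if (nrow(drug)) {
      drug[, tid := seq_len(.N)]
      drug[, n_fills := sample(1:3, .N, replace = TRUE,
                               prob = c(0.40, 0.35, 0.25))]
      fr <- rep(seq_len(nrow(drug)), drug$n_fills)
      fills <- drug[fr, .(tid, patient_id, eid, code, init_date, start_date,
                          span, cutoff)]
      fills[, supply := sample(c(30L, 90L, 100L), .N, replace = TRUE,
                               prob = c(0.45, 0.30, 0.25))]
      fills[, date := init_date +
              c(0, cumsum(supply[-.N]))[seq_len(.N)], by = tid]
      fills <- fills[date <= start_date + span]    # keep quiet gaps quiet
      fills[, daily_dose_mg := data.table::fifelse(
        code == "N05AH04",
        sample(c(150, 200, 300), .N, replace = TRUE), NA_real_)]
    }
  }

  ## ---- depression-related diagnosis events --------------------------------
  dep_ev <- list()
  # opening diagnosis
  dep_ev$open <- ep[, .(patient_id, eid, date = start_date,
                        icd10 = data.table::fifelse(episode_number == 1L,
                                                    "F32.1", "F33.1"),
                        care_setting = data.table::fifelse(care_psychiatric,
                                                           "psychiatric",
                                                           "nonpsychiatric"),
                        locus = "outpatient", discharge_date = as.Date(NA))]
  # follow-up visits every ~150 days plus a closing visit at the span end
  nfill <- pmax(0L, floor(ep$span / 150))
  if (sum(nfill) > 0) {
    fi <- rep(seq_len(m), nfill)
    k <- sequence(nfill)
    offs <- pmin(pmax(1, round(k * 150 + stats::runif(length(k), -30, 30))),
                 ep$span[fi] - 1)
    dep_ev$fill <- data.table::data.table(
      patient_id = ep$patient_id[fi], eid = ep$eid[fi],
      date = ep$start_date[fi] + offs, icd10 = "F32.9",
      care_setting = ifelse(stats::runif(length(k)) <
                              ifelse(ep$planted[fi], 0.6, 0.3),
                            "psychiatric", "nonpsychiatric"),
      locus = "outpatient", discharge_date = as.Date(NA))
  }
  dep_ev$close <- ep[, .(patient_id, eid, date = start_date + span,
                         icd10 = "F32.9",
                         care_setting = data.table::fifelse(planted,
                                                            "psychiatric",
                                                            "nonpsychiatric"),
                         locus = "outpatient", discharge_date = as.Date(NA))]
  # inpatient admissions (depression), more for the TRD track after index
  n_adm <- stats::rpois(m, 0.2 + 0.6 * ep$planted)
  if (sum(n_adm) > 0) {
    ai <- rep(seq_len(m), n_adm)
    lo <- ifelse(ep$planted[ai], pmax(0, ep$o3[ai] - 360), 0)
    offs <- round(lo + stats::runif(length(ai)) * pmax(1, ep$span[ai] - lo))
    offs <- pmin(offs, ep$span[ai])
    los <- pmax(1, round(stats::rlnorm(length(ai), log(7), 0.6)))
    dep_ev$inpat <- data.table::data.table(
      patient_id = ep$patient_id[ai], eid = ep$eid[ai],
      date = ep$start_date[ai] + offs, icd10 = "F32.2",
      care_setting = "psychiatric", locus = "inpatient",
      discharge_date = ep$start_date[ai] + offs + los)
  }
  dep_dx <- data.table::rbindlist(dep_ev, use.names = TRUE)

  ## ---- procedures ----------------------------------------------------------
  proc <- list()
  if (!is.null(tr)) {
    ect <- tr[class == "ECT_rTMS"]
    if (nrow(ect)) {
      ns <- sample(4:6, nrow(ect), replace = TRUE)
      si <- rep(seq_len(nrow(ect)), ns)
      sess_off <- (sequence(ns) - 1L) * 2L
      proc$ect <- data.table::data.table(
        patient_id = ect$patient_id[si], eid = ect$eid[si],
        date = ect$init_date[si] + sess_off, procedure = ect$code[si])
    }
  }
  n_pt <- stats::rpois(m, 1.6 * (stats::runif(m) < 0.40))
  if (sum(n_pt) > 0) {
    pi_ <- rep(seq_len(m), n_pt)
    proc$pt <- data.table::data.table(
      patient_id = ep$patient_id[pi_], eid = ep$eid[pi_],
      date = ep$start_date[pi_] +
        floor(stats::runif(length(pi_)) * (ep$span[pi_] + 1)),
      procedure = "psychotherapy")
  }
  proc <- if (length(proc)) data.table::rbindlist(proc, use.names = TRUE) else NULL

  ## ---- noise dispensations -------------------------------------------------
  noise_rx <- list()
  pre_noise <- ep$episode_number == 1L & stats::runif(m) < 0.10
  if (any(pre_noise)) {
    ni <- which(pre_noise)
    noise_rx$pre <- data.table::data.table(
      patient_id = ep$patient_id[ni],
      date = ep$start_date[ni] - round(stats::runif(length(ni), 45, 90)),
      atc = "N06AA02", supply_days = 30L, daily_dose_mg = NA_real_)
  }
  # low-dose quetiapine: exercises the >100 mg add-on floor without ever
  # qualifying as a trial
  has_quet <- if (!is.null(tr)) unique(tr$eid[tr$code == "N05AH04"]) else integer(0)
  quet_noise <- ep$treated & !(ep$eid %in% has_quet) & stats::runif(m) < 0.05
  if (any(quet_noise)) {
    qi <- which(quet_noise)
    noise_rx$quet <- data.table::data.table(
      patient_id = ep$patient_id[qi],
      date = ep$start_date[qi] +
        floor(stats::runif(length(qi)) * pmax(1, ep$span[qi] - 30)),
      atc = "N05AH04", supply_days = 30L, daily_dose_mg = 100)
  }
  quet_eids <- if (any(quet_noise)) ep$eid[quet_noise] else integer(0)

  ## ---- comorbidity and utilization events ---------------------------------
  com <- list()
  cr <- config$comorbidity_rates
  anx <- which(ep$anxiety_flag)
  if (length(anx)) {
    use_rx <- stats::runif(length(anx)) < 0.30
    d <- ep$start_date[anx] - round(stats::runif(length(anx), 30, 1000))
    com$anx_dx <- data.table::data.table(
      patient_id = ep$patient_id[anx][!use_rx], date = d[!use_rx],
      icd10 = "F41.1", care_setting = "nonpsychiatric", locus = "outpatient",
      discharge_date = as.Date(NA))
    noise_rx$anxiolytic <- data.table::data.table(
      patient_id = ep$patient_id[anx][use_rx], date = d[use_rx],
      atc = "N05BA04", supply_days = 30L, daily_dose_mg = NA_real_)
  }
  slp <- which(ep$sleep_flag)
  if (length(slp)) {
    use_rx <- stats::runif(length(slp)) < 0.30
    d <- ep$start_date[slp] - round(stats::runif(length(slp), 30, 1000))
    com$slp_dx <- data.table::data.table(
      patient_id = ep$patient_id[slp][!use_rx], date = d[!use_rx],
      icd10 = "G47.0", care_setting = "nonpsychiatric", locus = "outpatient",
      discharge_date = as.Date(NA))
    noise_rx$sedative <- data.table::data.table(
      patient_id = ep$patient_id[slp][use_rx], date = d[use_rx],
      atc = "N05CF01", supply_days = 30L, daily_dose_mg = NA_real_)
  }
  # substance-use history (no planted TRD effect; candidate-variable noise)
  sub <- which(stats::runif(m) < stats::plogis(-2.2 + 0.5 * ep$severity))
  if (length(sub)) {
    com$sub_dx <- data.table::data.table(
      patient_id = ep$patient_id[sub],
      date = ep$start_date[sub] - round(stats::runif(length(sub), 30, 1000)),
      icd10 = "F10.2", care_setting = "psychiatric", locus = "outpatient",
      discharge_date = as.Date(NA))
  }
  # pre-start outpatient contacts realising the visits_12m covariate
  if (sum(ep$visits_12m) > 0) {
    pv <- rep(seq_len(m), ep$visits_12m)
    com$previsits <- data.table::data.table(
      patient_id = ep$patient_id[pv],
      date = ep$start_date[pv] - sample(1:365, length(pv), replace = TRUE),
      icd10 = sample(c("Z00.0", "M54.5", "J06.9"), length(pv), replace = TRUE),
      care_setting = "nonpsychiatric", locus = "outpatient",
      discharge_date = as.Date(NA))
  }
  # anxiety/stress onsets around the index date: the planted arm gets more
  anchor <- data.table::fifelse(ep$planted, ep$o3,
                                pmin(ep$span, 400))
  p_onset <- data.table::fifelse(ep$planted, cr[["onset_trd"]],
                                 cr[["onset_non_trd"]])
  for (cond in c("F41.1", "F43.1")) {
    hit <- which(stats::runif(m) < p_onset)
    if (length(hit)) {
      com[[cond]] <- data.table::data.table(
        patient_id = ep$patient_id[hit],
        date = ep$start_date[hit] + round(anchor[hit] +
                                            stats::runif(length(hit), -330, 330)),
        icd10 = cond, care_setting = "psychiatric", locus = "outpatient",
        discharge_date = as.Date(NA))
    }
  }
  # generic outpatient visits (utilization noise, higher on the TRD track)
  n_vis <- stats::rpois(m, pmax(0.3, ep$span / 365) * (4 + 4 * ep$planted))
  if (sum(n_vis) > 0) {
    vi <- rep(seq_len(m), n_vis)
    com$visits <- data.table::data.table(
      patient_id = ep$patient_id[vi],
      date = ep$start_date[vi] + floor(stats::runif(length(vi)) *
                                         (ep$span[vi] + 1)),
      icd10 = sample(c("Z00.0", "M54.5", "J06.9"), length(vi),
                     replace = TRUE),
      care_setting = ifelse(stats::runif(length(vi)) < 0.25,
                            "psychiatric", "nonpsychiatric"),
      locus = "outpatient", discharge_date = as.Date(NA))
  }
  # exclusion diagnoses for flagged patients
  exc <- pat[excl_dx == TRUE]
  if (nrow(exc)) {
    com$excl <- data.table::data.table(
      patient_id = exc$patient_id,
      date = pmin(exc$cutoff,
                  exc$first_start + round(stats::runif(nrow(exc), -400, 400))),
      icd10 = sample(c("F31.0", "F20.9", "F30.1", "F03"), nrow(exc),
                     replace = TRUE),
      care_setting = "psychiatric", locus = "outpatient",
      discharge_date = as.Date(NA))
  }
  # intentional self-harm (first-ever record drives the survival outcome)
  trk <- pat$patient_id %in% ep$patient_id[ep$planted]
  sh_rate <- ifelse(trk, config$selfharm_rate_trd, config$selfharm_rate_non_trd)
  sh_years <- pmax(0, as.numeric(pat$cutoff - pat$first_start)) / 365.25
  n_sh <- stats::rpois(nrow(pat), sh_rate / 1000 * sh_years)
  if (sum(n_sh) > 0) {
    si <- rep(seq_len(nrow(pat)), n_sh)
    u <- stats::runif(length(si))
    loc <- stats::runif(length(si))
    com$selfharm <- data.table::data.table(
      patient_id = pat$patient_id[si],
      date = pat$first_start[si] +
        floor(u * pmax(1, as.numeric(pat$cutoff[si] - pat$first_start[si]))),
      icd10 = paste0("X", sample(60:84, length(si), replace = TRUE)),
      care_setting = ifelse(loc < 0.85, "psychiatric", "nonpsychiatric"),
      locus = ifelse(loc < 0.50, "inpatient", "outpatient"),
      discharge_date = as.Date(NA))
  }
  com_dx <- data.table::rbindlist(com, use.names = TRUE, fill = TRUE)

  ## ---- sick leave ----------------------------------------------------------
  n_sl <- stats::rpois(m, 0.7 + 0.6 * ep$planted)
  sick <- NULL
  if (sum(n_sl) > 0) {
    li <- rep(seq_len(m), n_sl)
    s0 <- ep$start_date[li] + floor(stats::runif(length(li)) * (ep$span[li] + 1))
    dur <- pmax(1, round(stats::rlnorm(length(li), log(25), 0.9)))
    sick <- data.table::data.table(patient_id = ep$patient_id[li],
                                   start_date = s0, end_date = s0 + dur)
  }

  ## ---- MADRS-S ratings with MAR deletion ----------------------------------
  rate_day <- ep$start_date - sample(1:14, m, replace = TRUE)
  miss <- rep(TRUE, m)
  if (config$madrs_missing_rate >= 1) {
    # everything deleted
  } else if (config$madrs_missing_rate <= 0) {
    miss <- rep(FALSE, m)
  } else {
    lv2 <- log1p(ep$visits_12m)
    zmiss <- 1.0 * ep$care_psychiatric + 0.35 * (lv2 - mean(lv2))
    a_miss <- calibrate_intercept(zmiss, config$madrs_missing_rate)
    miss <- stats::runif(m) < stats::plogis(a_miss + zmiss)
  }
  ratings <- data.table::data.table(patient_id = ep$patient_id,
                                    date = rate_day,
                                    score = as.numeric(ep$madrs_true))[!miss]

  ## ---- assemble, truncate at each patient's cutoff -------------------------
  cut <- pat[, .(patient_id, cutoff)]
  clip <- function(d) {
    d <- d[cut, on = "patient_id", cut_ := i.cutoff]
    d <- d[date <= cut_]
    d[, cut_ := NULL]
    d
  }
  dep_dx <- clip(dep_dx)
  dep_dx[!is.na(discharge_date), discharge_date := {
    pm <- cut$cutoff[match(patient_id, cut$patient_id)]
    pmin(discharge_date, pm)
  }]
  com_dx <- clip(com_dx)
  diagnoses <- data.table::rbindlist(list(
    dep_dx[, .(patient_id, date, icd10, care_setting, locus, discharge_date)],
    com_dx[, .(patient_id, date, icd10, care_setting, locus, discharge_date)]),
    use.names = TRUE)
  data.table::setorder(diagnoses, patient_id, date, icd10)

  rx <- list()
  if (!is.null(fills))
    rx$fills <- fills[, .(patient_id, date, atc = code,
                          supply_days = supply, daily_dose_mg)]
  for (nm in names(noise_rx))
    rx[[nm]] <- noise_rx[[nm]][, .(patient_id, date, atc,
                                   supply_days = as.integer(supply_days),
                                   daily_dose_mg)]
  dispensations <- if (length(rx)) {
    clip(data.table::rbindlist(rx, use.names = TRUE))
  } else {
    empty_cohort_tables()$dispensations
  }
  data.table::setorder(dispensations, patient_id, date, atc)

  procedures <- if (!is.null(proc)) {
    clip(proc)[, .(patient_id, date, procedure)]
  } else {
    empty_cohort_tables()$procedures
  }
  data.table::setorder(procedures, patient_id, date, procedure)

  if (!is.null(sick)) {
    sick <- sick[cut, on = "patient_id", cut_ := i.cutoff]
    sick <- sick[start_date <= cut_]
    sick[, end_date := pmin(end_date, cut_)]
    sick[, cut_ := NULL]
  } else sick <- empty_cohort_tables()$sick_leave
  data.table::setorder(sick, patient_id, start_date)

  ratings <- ratings[cut, on = "patient_id", cut_ := i.cutoff][date <= cut_]
  ratings[, cut_ := NULL]
  data.table::setorder(ratings, patient_id, date)

  demographics <- pat[, .(patient_id, birth_date, sex, ses = as.integer(ses),
                          residency_start, residency_end)]
  vital <- pat[, .(patient_id, death_date)]

  ## ---- ground truth after truncation --------------------------------------
  # episode end = last surviving depression-related event on/after the start
  dep_all <- list(dep_dx[, .(eid, date)])
  if (!is.null(fills)) {
    f2 <- clip(fills[, .(patient_id, eid, date)])
    dep_all$fills <- f2[, .(eid, date)]
  }
  if (!is.null(proc)) {
    p2 <- clip(proc[, .(patient_id, eid, date)])
    dep_all$proc <- p2[, .(eid, date)]
  }
  if (any(quet_noise)) {
    q2 <- clip(noise_rx$quet[, .(patient_id, date)][, eid := quet_eids])
    dep_all$quet <- q2[, .(eid, date)]
  }
  dep_all <- data.table::rbindlist(dep_all, use.names = TRUE)
  ends <- dep_all[ep[, .(eid, start_date)], on = "eid"][date >= start_date,
                                                        .(end_date = max(date)),
                                                        by = eid]
  gt <- ep[, .(patient_id, episode_number, eid, start_date, treated,
               severity, madrs_true = as.numeric(madrs_true),
               care_psychiatric, visits_12m = as.integer(visits_12m),
               anxiety_flag, sleep_flag, eligible, planted, o1, o2, o3,
               cutoff, n_trials_gen)]
  gt[ends, on = "eid", end_date := i.end_date]
  gt[is.na(end_date), end_date := start_date]
  # surviving trial count and demotion of truncated planted labels
  if (!is.null(tr)) {
    tsurv <- tr[init_date <= cutoff, .(n_trials = .N), by = eid]
    gt[tsurv, on = "eid", n_trials := i.n_trials]
  }
  if (!"n_trials" %in% names(gt)) gt[, n_trials := NA_integer_]
  gt[is.na(n_trials), n_trials := 0L]
  gt[, planted_trd := planted & n_trials >= 3L]
  gt[, trd_index_date := data.table::fifelse(planted_trd,
                                             start_date + o3, as.Date(NA))]
  gt[, time_to_trd_days := data.table::fifelse(planted_trd, o3, NA_real_)]
  gt_ep <- gt[, .(patient_id, episode_number, start_date, end_date, treated,
                  planted_track = planted,
                  planted_trd, trd_index_date, time_to_trd_days, n_trials,
                  severity, madrs_true, care_psychiatric, visits_12m,
                  anxiety_flag, sleep_flag, eligible)]
  gt_pat <- pat[, .(patient_id, hazard_multiplier, death_date, cutoff)]

  structure(list(
    tables = list(demographics = demographics, diagnoses = diagnoses,
                  dispensations = dispensations, procedures = procedures,
                  sick_leave = sick, ratings = ratings, vital_status = vital),
    ground_truth = list(episodes = gt_ep, patients = gt_pat,
                        true_coefficients = true_coefs),
    config = config), class = "trd_cohort")
}

#' @export
print.trd_cohort <- function(x, ...) {
  cat("Synthetic TRD registry cohort\n")
  cat(sprintf("  patients: %d\n", nrow(x$tables$demographics)))
  cat(sprintf("  episodes (ground truth): %d, planted TRD: %d\n",
              nrow(x$ground_truth$episodes),
              sum(x$ground_truth$episodes$planted_trd)))
  for (nm in names(x$tables))
    cat(sprintf("  %-13s %8d rows\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

# deterministic polynomial hash of the deparsed config (no external digest
# dependency); arithmetic kept within exact double-precision integer range
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write cohort tables to delimited text files
#'
#' One UTF-8 CSV per table with ISO-8601 dates, plus a `manifest.csv` listing
#' file names, row counts and a deterministic hash of the generating
#' configuration.
#'
#' @param cohort a `trd_cohort` object (or a bare named list of tables, in
#'   which case the config hash is empty).
#' @param directory output directory; created if needed.
#' @return the manifest data.table, invisibly written as `manifest.csv`.
#' @export
write_cohort_tables <- function(cohort, directory) {
  tables <- if (inherits(cohort, "trd_cohort")) cohort$tables else cohort
  cfg <- if (inherits(cohort, "trd_cohort")) cohort$config else NULL
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop(sprintf("cannot create or write to directory '%s'", directory),
         call. = FALSE)
  hash <- if (is.null(cfg)) "" else config_hash(cfg)
  rows <- integer(0)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(directory, paste0(nm, ".csv"))
    data.table::fwrite(tables[[nm]], f, dateTimeAs = "ISO")
    files <- c(files, basename(f))
    rows <- c(rows, nrow(tables[[nm]]))
  }
  manifest <- data.table::data.table(table = names(tables), file = files,
                                     rows = rows, config_hash = hash)
  data.table::fwrite(manifest, file.path(directory, "manifest.csv"))
  invisible(manifest)
}

#' Read cohort tables back from a directory
#'
#' Inverse of [write_cohort_tables()]: reads the seven registry CSVs with
#' their documented column types (dates parsed as `Date`).
#'
#' @param directory directory containing the CSV files.
#' @return named list of data.tables.
#' @export
read_cohort_tables <- function(directory) {
  protos <- cohort_table_protos()
  out <- list()
  for (nm in names(protos)) {
    f <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(f)) next
    proto <- protos[[nm]]
    cc <- ifelse(proto == "Date", "character", proto)
    d <- data.table::fread(f, colClasses = stats::setNames(as.character(cc),
                                                           names(proto)))
    for (col in names(proto)[proto == "Date"])
      data.table::set(d, j = col, value = as.Date(d[[col]]))
    out[[nm]] <- d
  }
  out
}
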