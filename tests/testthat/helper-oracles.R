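# Independent brute-force reference implementations used to cross-check the
# vectorised pipeline, plus small random-instance generators. These are
# written as plain loops over explicit day sets, deliberately sharing no
# code with the package internals.

# --- episode construction oracle -------------------------------------------
# events: data.frame(date (integer day), opens (logical: F32/F33 diagnosis),
# dep (logical: depression-related)) for ONE patient, any order.
oracle_episodes_one <- function(day, opens, dep, gap_days = 365) {
  o <- order(day)
  day <- day[o]; opens <- opens[o]; dep <- dep[o]
  keep <- dep
  day <- day[keep]; opens <- opens[keep]
  eps <- list()
  cur_start <- NA; cur_last <- NA
  for (i in seq_along(day)) {
    if (!is.na(cur_start) && day[i] - cur_last >= gap_days) {
      eps[[length(eps) + 1L]] <- c(cur_start, cur_last)
      cur_start <- NA; cur_last <- NA
    }
    if (!is.na(cur_start)) {
      cur_last <- day[i]
    } else if (opens[i]) {
      cur_start <- day[i]; cur_last <- day[i]
    }
  }
  if (!is.na(cur_start)) eps[[length(eps) + 1L]] <- c(cur_start, cur_last)
  if (!length(eps)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, eps)
}

# --- trial identification oracle -------------------------------------------
# Day-set exposure construction and explicit greedy acceptance.
# disp: data.frame(atc, day, supply, dose); procs: data.frame(label, day)
oracle_trials_one <- function(disp, procs, ep_start, ep_end,
                              gap_days = 28, min_dur = 28, grace = 30,
                              addons = c("N05AX12", "N05AN01", "N05AH03",
                                         "N05AH04", "N05AX08"),
                              ect_gap = 14) {
  cand <- list()
  if (!is.null(disp) && nrow(disp)) {
    for (drug in sort(unique(disp$atc))) {
      is_ad <- startsWith(drug, "N06A") || drug %in% addons
      if (!is_ad) next
      dd <- disp[disp$atc == drug, , drop = FALSE]
      dd <- dd[order(dd$day, -dd$supply), , drop = FALSE]
      days <- sort(unique(unlist(lapply(seq_len(nrow(dd)), function(i)
        dd$day[i]:(dd$day[i] + dd$supply[i] - 1L)))))
      splits <- which(diff(days) > grace)
      run_id <- cumsum(c(1L, as.integer(seq_along(days)[-1] %in% (splits + 1L))))
      for (r in unique(run_id)) {
        d_r <- days[run_id == r]
        s <- min(d_r); e <- max(d_r)
        if (s < ep_start || s > ep_end) next
        if ((e - s + 1L) < min_dur) next
        if (drug == "N05AH04") {
          d0 <- dd[dd$day == s, , drop = FALSE]
          dose <- d0$dose[1]
          if (is.na(dose) || dose <= 100) next
        }
        cand[[length(cand) + 1L]] <- data.frame(
          day = s, proc = FALSE, dur = e - s + 1L, key = drug)
      }
    }
  }
  if (!is.null(procs) && nrow(procs)) {
    for (lab in sort(unique(procs$label))) {
      if (!lab %in% c("ECT", "rTMS")) next
      dd <- sort(procs$day[procs$label == lab])
      course_start <- dd[1]
      prev <- dd[1]
      starts <- c()
      for (d in dd) {
        if (d - prev > ect_gap) {
          starts <- c(starts, course_start)
          course_start <- d
        }
        prev <- d
      }
      starts <- c(starts, course_start)
      for (s in starts) {
        if (s >= ep_start && s <= ep_end)
          cand[[length(cand) + 1L]] <- data.frame(
            day = s, proc = TRUE, dur = NA_real_, key = lab)
      }
    }
  }
  if (!length(cand)) return(data.frame(day = numeric(0), key = character(0)))
  cand <- do.call(rbind, cand)
  # candidate order: day, procedures first, longer duration, lexicographic key
  cand <- cand[order(cand$day, !cand$proc, -ifelse(is.na(cand$dur), Inf,
                                                   cand$dur), cand$key), ,
               drop = FALSE]
  acc <- data.frame(day = numeric(0), key = character(0))
  last_init <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$proc[i] || !is.finite(last_init) ||
        cand$day[i] - last_init > gap_days) {
      acc <- rbind(acc, data.frame(day = cand$day[i], key = cand$key[i]))
      last_init <- max(last_init, cand$day[i])
    }
  }
  acc
}

# --- Kaplan-Meier product-limit oracle -------------------------------------
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# --- Harrell concordance oracle (all pairs) --------------------------------
oracle_concordance <- function(time, event, score) {
  conc <- 0; ties <- 0; usable <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # the pair is usable if the shorter time is an event
      ti <- time[i]; tj <- time[j]
      if (ti == tj && event[i] && event[j]) next  # tied event times: skipped
      if (ti < tj && event[i]) {
        usable <- usable + 1
        if (score[i] > score[j]) conc <- conc + 1
        else if (score[i] == score[j]) ties <- ties + 1
      } else if (tj < ti && event[j]) {
        usable <- usable + 1
        if (score[j] > score[i]) conc <- conc + 1
        else if (score[i] == score[j]) ties <- ties + 1
      }
    }
  }
  (conc + 0.5 * ties) / usable
}

# --- random small-instance generators --------------------------------------
random_event_stream <- function(n_events, origin = as.Date("2014-01-01")) {
  kinds <- sample(c("dx", "rx", "proc", "other"), n_events, replace = TRUE,
                  prob = c(0.4, 0.3, 0.15, 0.15))
  day <- sort(sample.int(1500, n_events, replace = TRUE))
  data.frame(
    day = day,
    kind = ifelse(kinds == "rx", "dispensation",
                  ifelse(kinds == "proc", "procedure", "diagnosis")),
    code = ifelse(kinds == "dx", sample(c("F32.0", "F33.1"), n_events, TRUE),
                  ifelse(kinds == "rx", sample(c("N06AB06", "N06AX11",
                                                 "N05AH03"), n_events, TRUE),
                         ifelse(kinds == "proc",
                                sample(c("ECT", "psychotherapy"), n_events, TRUE),
                                sample(c("F41.1", "Z00.0"), n_events, TRUE)))),
    stringsAsFactors = FALSE)
}

random_trial_instance <- function() {
  n_rx <- sample(0:8, 1)
  n_pr <- sample(0:3, 1)
  ep_start <- 100L
  ep_end <- ep_start + sample(100:900, 1)
  disp <- if (n_rx > 0) data.frame(
    atc = sample(c("N06AB06", "N06AB10", "N06AX11", "N05AH04", "N05AN01",
                   "N05CF01"), n_rx, replace = TRUE),
    day = sample.int(1100, n_rx, replace = TRUE),
    supply = sample(c(10L, 28L, 30L, 90L, 100L), n_rx, replace = TRUE),
    dose = sample(c(NA, 100, 150, 300), n_rx, replace = TRUE)) else NULL
  procs <- if (n_pr > 0) data.frame(
    label = sample(c("ECT", "rTMS"), n_pr, replace = TRUE),
    day = sample.int(1100, n_pr, replace = TRUE)) else NULL
  list(disp = disp, procs = procs, ep_start = ep_start, ep_end = ep_end)
}

# run the package pipeline on one random trial instance (via real tables)
run_trials_pkg <- function(inst, origin = as.Date("2010-01-01")) {
  ep <- data.table::data.table(patient_id = 1L, episode_id = 1L,
                               start_date = origin + inst$ep_start,
                               end_date = origin + inst$ep_end)
  disp <- if (!is.null(inst$disp)) data.frame(
    patient_id = 1L, date = origin + inst$disp$day, atc = inst$disp$atc,
    supply_days = inst$disp$supply, daily_dose_mg = inst$disp$dose) else NULL
  procs <- if (!is.null(inst$procs)) data.frame(
    patient_id = 1L, date = origin + inst$procs$day,
    procedure = inst$procs$label) else NULL
  ex <- estimate_exposure(disp)
  identify_trials(ep, ex, procs)
}

# quick synthetic matched cohort for outcome tests
tiny_matched <- function(n_sets = 20, origin = as.Date("2015-01-01")) {
  rows <- list()
  eid <- 0L
  for (s in seq_len(n_sets)) {
    for (r in c("case", "control", "control")) {
      eid <- eid + 1L
      rows[[eid]] <- data.frame(set_id = s, episode_id = eid,
                                patient_id = eid, role = r,
                                is_trd = r == "case",
                                start_date = origin,
                                end_date = origin + 400,
                                index_date = origin + 100)
    }
  }
  do.call(rbind, rows)
}
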