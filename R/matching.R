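#' Exact-match TRD episodes to non-TRD control episodes
#'
#' Each TRD episode (case) is matched with up to `ratio` non-TRD episodes
#' that agree exactly on sex, socioeconomic category and number of previous
#' MDD episodes, are within 5 years of age at the case's index date, have at
#' least one valid antidepressant treatment trial, and last at least as long
#' as the time from the case's episode start to its TRD index date. Controls
#' are used without replacement across sets; cases are processed in seeded
#' random order so control depletion is not systematic. The sensitivity mode
#' drops the treatment-initiation and duration requirements.
#'
#' @param status classified episode table ([classify_trd()] output after
#'   exclusions), one row per episode with `episode_id`, `patient_id`,
#'   `episode_number`, `start_date`, `end_date`, `is_trd`, `index_date`,
#'   `n_trials`.
#' @param demographics table with `patient_id`, `sex`, `ses`, `birth_date`.
#' @param ratio maximum controls per case (default 5).
#' @param seed RNG seed controlling case order and control sampling.
#' @param mode `"primary"` (treatment + duration criteria) or
#'   `"sensitivity"` (exact keys and age caliper only).
#' @param age_caliper_years age caliper half-width in years.
#' @return list of class `trd_matches`: `sets` (one row per matched episode:
#'   `set_id`, `episode_id`, `patient_id`, `role`, `is_trd`), `unmatched`
#'   (case episode ids with no eligible control), and the matching settings.
#' @export
match_episodes <- function(status, demographics, ratio = 5L, seed = 1L,
                           mode = c("primary", "sensitivity"),
                           age_caliper_years = 5) {
  mode <- match.arg(mode)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 1)
    stop_field("ratio", "must be a count >= 1")
  st <- data.table::as.data.table(status)
  require_columns(st, c("episode_id", "patient_id", "episode_number",
                        "start_date", "end_date", "is_trd", "index_date",
                        "n_trials"), "status")
  dem <- data.table::as.data.table(demographics)
  require_columns(dem, c("patient_id", "sex", "ses", "birth_date"),
                  "demographics")
  st <- data.table::copy(st)
  st[dem, on = "patient_id", `:=`(sex = i.sex, ses = i.ses,
                                  birth_date = as_day(i.birth_date))]
  st[, prior_episodes := episode_number - 1L]
  st[, duration := as.numeric(end_date - start_date)]

  cases <- st[is_trd == TRUE]
  cands <- st[is_trd == FALSE]
  if (mode == "primary") cands <- cands[n_trials >= 1L]
  empty_sets <- data.table::data.table(set_id = integer(0),
                                       episode_id = integer(0),
                                       patient_id = integer(0),
                                       role = character(0),
                                       is_trd = logical(0))
  if (!nrow(cases) || !nrow(cands)) {
    return(structure(list(sets = empty_sets,
                          unmatched = cases$episode_id,
                          ratio = ratio, mode = mode, seed = seed),
                     class = "trd_matches"))
  }
  cases[, tti := as.numeric(index_date - start_date)]

  pairs <- cands[cases,
                 on = .(sex, ses, prior_episodes),
                 allow.cartesian = TRUE, nomatch = NULL,
                 .(case_id = i.episode_id, cand_id = x.episode_id,
                   age_gap = abs(as.numeric(x.birth_date - i.birth_date)),
                   duration = x.duration, tti = i.tti)]
  pairs <- pairs[age_gap <= age_caliper_years * 365.25]
  if (mode == "primary") pairs <- pairs[duration >= tti]

  set.seed(seed)
  order_cases <- cases$episode_id[sample.int(nrow(cases))]
  by_case <- split(pairs$cand_id, pairs$case_id)
  used <- new.env(parent = emptyenv())
  sets <- vector("list", length(order_cases))
  unmatched <- integer(0)
  sid <- 0L
  for (cid in order_cases) {
    elig <- by_case[[as.character(cid)]]
    if (!is.null(elig)) {
      free <- elig[vapply(as.character(elig),
                          function(k) is.null(used[[k]]), logical(1))]
    } else free <- integer(0)
    if (!length(free)) {
      unmatched <- c(unmatched, cid)
      next
    }
    k <- min(length(free), ratio)
    pick <- free[sample.int(length(free), k)]
    for (p in as.character(pick)) used[[p]] <- TRUE
    sid <- sid + 1L
    sets[[sid]] <- data.table::data.table(
      set_id = sid, episode_id = c(cid, pick),
      role = c("case", rep("control", k)))
  }
  sets <- if (sid > 0L) data.table::rbindlist(sets[seq_len(sid)]) else empty_sets
  if (nrow(sets)) {
    sets[st, on = "episode_id", `:=`(patient_id = i.patient_id,
                                     is_trd = i.is_trd)]
    data.table::setcolorder(sets, c("set_id", "episode_id", "patient_id",
                                    "role", "is_trd"))
  }
  structure(list(sets = sets, unmatched = unmatched, ratio = ratio,
                 mode = mode, seed = seed),
            class = "trd_matches")
}

#' @export
print.trd_matches <- function(x, ...) {
  nc <- sum(x$sets$role == "case")
  nk <- sum(x$sets$role == "control")
  cat(sprintf("Matched TRD cohort (%s mode, ratio <= %d)\n", x$mode, x$ratio))
  cat(sprintf("  %d cases, %d controls (achieved ratio %.2f), %d unmatched cases\n",
              nc, nk, if (nc) nk / nc else NA_real_, length(x$unmatched)))
  invisible(x)
}

#' Assign index dates to matched episodes
#'
#' Cases keep their TRD index date. In `"calendar"` mode (the default,
#' literal reading of giving controls "the same index date") every control
#' receives its case's calendar index date. In `"offset"` mode a control's
#' index is its own episode start plus the case's start-to-index interval,
#' which the primary matching duration criterion guarantees to fall inside
#' the control episode.
#'
#' @param matches a `trd_matches` object.
#' @param status the classified episode table used for matching.
#' @param mode `"calendar"` or `"offset"`.
#' @return data.table, one row per matched episode: set/episode/patient ids,
#'   `role`, `is_trd`, `start_date`, `end_date`, `index_date`; the index
#'   mode is recorded in the `index_mode` attribute.
#' @export
assign_index_dates <- function(matches, status, mode = c("calendar", "offset")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matches, "trd_matches"))
  st <- data.table::as.data.table(status)
  out <- data.table::copy(matches$sets)
  if (!nrow(out)) {
    out[, `:=`(start_date = as.Date(character(0)),
               end_date = as.Date(character(0)),
               index_date = as.Date(character(0)))]
    data.table::setattr(out, "index_mode", mode)
    return(out[])
  }
  out[st, on = "episode_id", `:=`(start_date = i.start_date,
                                  end_date = i.end_date,
                                  index_date = i.index_date)]
  case_idx <- out[role == "case", .(set_id, case_index = index_date,
                                    case_tti = as.numeric(index_date - start_date))]
  out[case_idx, on = "set_id", `:=`(case_index = i.case_index,
                                    case_tti = i.case_tti)]
  if (mode == "calendar") {
    out[role == "control", index_date := case_index]
  } else {
    out[role == "control", index_date := start_date + case_tti]
    bad <- out[role == "control" &
                 as.numeric(end_date - start_date) < case_tti]
    if (nrow(bad))
      stop("offset index mode: some controls are shorter than the case ",
           "start-to-index interval (sensitivity-matched sets cannot use ",
           "offset mode)", call. = FALSE)
  }
  out[, c("case_index", "case_tti") := NULL]
  data.table::setattr(out, "index_mode", mode)
  out[]
}
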