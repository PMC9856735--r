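#' Map treatment codes to treatment classes
#'
#' Vectorised lookup of the treatment group (SSRI, NaSSA, SNRI, NDRI, TCA,
#' add-on, agomelatine, vortioxetine, other antidepressant, ECT/rTMS) for
#' ATC codes and procedure labels. Quetiapine maps to `add_on` only when the
#' daily dose exceeds the floor; at or below it the code falls back to
#' `other_AD`. Unmapped codes map to `other_AD` with a warning, or raise an
#' error in strict mode.
#'
#' @param treatment_key character vector of ATC codes / procedure labels.
#' @param daily_dose_mg optional numeric vector (recycled) of daily doses.
#' @param map class map, see [default_treatment_classes()].
#' @param quetiapine_min_dose_mg dose floor for the add-on mapping.
#' @param strict error on unmapped codes instead of warning.
#' @return character vector of classes.
#' @export
classify_treatment <- function(treatment_key, daily_dose_mg = NULL,
                               map = default_treatment_classes(),
                               quetiapine_min_dose_mg = 100,
                               strict = FALSE) {
  cls <- map$class[match(treatment_key, map$code)]
  if (anyNA(cls)) {
    bad <- unique(treatment_key[is.na(cls)])
    if (strict)
      stop(sprintf("unmapped treatment code(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    warning(sprintf("unmapped treatment code(s) assigned to other_AD: %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
    cls[is.na(cls)] <- "other_AD"
  }
  if (!is.null(daily_dose_mg)) {
    dose <- rep_len(daily_dose_mg, length(treatment_key))
    low_quet <- treatment_key == "N05AH04" & cls == "add_on" &
      !(ifelse(is.na(dose), 0, dose) > quetiapine_min_dose_mg)
    cls[low_quet] <- "other_AD"
  }
  cls
}

#' Treatment-sequence paths to the third trial
#'
#' Aggregates the ordered class triples (trial 1, 2, 3) over TRD episodes:
#' the table behind an alluvial plot of treatment sequences until TRD
#' criteria are reached, the number of distinct sequences, and the marginal
#' class share at each trial position.
#'
#' @param trials output of [identify_trials()], restricted to TRD episodes;
#'   an input episode with fewer than 3 trials is an error.
#' @return list: `paths` (`class1`, `class2`, `class3`, `n`), `n_paths`
#'   (distinct sequences), `marginals` (`position`, `class`, `share`),
#'   `n_episodes`.
#' @export
sequence_paths <- function(trials) {
  tr <- data.table::as.data.table(trials)
  require_columns(tr, c("episode_id", "trial_index", "treatment_class"),
                  "trials")
  cnt <- tr[, .(k = max(trial_index)), by = episode_id]
  if (any(cnt$k < 3L))
    stop(sprintf("%d input episode(s) have fewer than 3 trials",
                 sum(cnt$k < 3L)), call. = FALSE)
  w <- data.table::dcast(tr[trial_index <= 3L], episode_id ~ trial_index,
                         value.var = "treatment_class")
  data.table::setnames(w, c("1", "2", "3"), c("class1", "class2", "class3"))
  paths <- w[, .(n = .N), by = .(class1, class2, class3)]
  data.table::setorder(paths, -n, class1, class2, class3)
  marg <- data.table::rbindlist(lapply(1:3, function(p) {
    v <- w[[paste0("class", p)]]
    t <- table(v) / length(v)
    data.table::data.table(position = p, class = names(t),
                           share = as.numeric(t))
  }))
  list(paths = paths[], n_paths = nrow(paths), marginals = marg[],
       n_episodes = nrow(w))
}
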