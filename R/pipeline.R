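#' Run the phenotyping pipeline end to end
#'
#' Convenience wrapper chaining the classification stages on a set of
#' registry tables: flatten events, build MDD episodes, apply the
#' inclusion/exclusion rules, estimate drug exposures, identify treatment
#' trials and classify TRD.
#'
#' @param tables registry tables (a `trd_cohort`'s `tables` element or the
#'   result of [read_cohort_tables()]).
#' @param gap_days episode quiet-gap threshold.
#' @param rules trial identification rules ([trd_rules()]).
#' @param episode_codes depression-related event definition.
#' @param lookback_months residency lookback for inclusion.
#' @return list: `episodes` (kept), `exclusion_log`, `exposures`, `trials`,
#'   `status` (classified episode table restricted to kept episodes).
#' @export
run_classification <- function(tables, gap_days = 365L, rules = trd_rules(),
                               episode_codes = default_episode_codes(),
                               lookback_months = 12) {
  if (inherits(tables, "trd_cohort")) tables <- tables$tables
  events <- as_clinical_events(tables)
  episodes <- build_episodes(events, gap_days = gap_days,
                             codes = episode_codes,
                             demographics = tables$demographics)
  excl <- apply_exclusions(episodes, tables$demographics, tables$diagnoses,
                           lookback_months = lookback_months)
  exposures <- estimate_exposure(tables$dispensations,
                                 grace_days = rules$grace_days)
  trials <- identify_trials(excl$kept, exposures, tables$procedures,
                            rules = rules)
  status <- classify_trd(trials, excl$kept)
  list(episodes = excl$kept, exclusion_log = excl$log, exposures = exposures,
       trials = trials, status = status)
}
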