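---
title: "Phenotyping and analysing treatment-resistant depression in registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping and analysing treatment-resistant depression in registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdcohort)
library(data.table)
```

## The problem

Treatment-resistant depression (TRD) is usually defined operationally: a
major depressive disorder (MDD) episode in which depression does not remit
after repeated adequate treatment attempts. In routine-care registries
nobody records "this patient is treatment resistant"; the phenotype has to
be *constructed* from dated event streams — diagnoses, drug dispensations,
procedures, sick-leave spells, symptom ratings. `trdcohort` implements that
construction and the downstream epidemiology as a tested, reusable
pipeline:

1. **Episodes.** An MDD episode opens at an ICD-10 F32/F33 diagnosis and
   closes at the last depression-related event followed by at least 365
   event-free days.
2. **Treatment trials and TRD.** Antidepressants (ATC N06A), qualifying
   add-ons (aripiprazole, lithium, olanzapine, quetiapine above 100 mg/day,
   risperidone) and ECT/rTMS count as treatment trials under duration and
   spacing rules; an episode reaching a **third** valid trial is TRD, and
   that trial's initiation date is the index date.
3. **Matched cohort.** Each TRD episode is exact-matched to up to five
   non-TRD episodes (sex, socioeconomic category, prior episode count, age
   within 5 years) that were treated with an antidepressant and lasted at
   least as long as the case's start-to-index interval.
4. **Outcomes.** Monthly (-12..+12) comorbidity, health-care-utilization
   and lost-workday profiles around the index date; cluster-robust Cox
   models for all-cause mortality and intentional self-harm; Kaplan-Meier
   episode duration; treatment-sequence (alluvial) tables.
5. **Prognosis.** A Cox risk score for TRD within one year of episode
   start, with chained-equations multiple imputation of the heavily missing
   MADRS-S severity score, step-down model approximation, bootstrap
   validation and a nomogram.

Because the registry this design comes from is not public, the package
ships a **synthetic registry generator** with planted ground truth; every
stage is tested against either hand-traceable examples, brute-force
re-implementations, or recovery of planted parameters.

## Rule details and numerical choices

All dates are whole calendar days; intervals are closed; gap arithmetic is
in integer days.

**Episode construction.** "Depression-related event" is not fully
specified by the case definition, so the package uses a configurable set
(F32/F33 diagnoses, N06A and add-on dispensations, ECT/rTMS/psychotherapy
contacts; `default_episode_codes()`). The quiet gap is measured from each
event to the next depression-related event, and a gap of 365 days or more
closes the episode. Whether psychotherapy contact alone extends an episode
is a flag (`include_psychotherapy`, default `TRUE`). Exclusions (age < 18
at start, 12 months or less of pre-start residency, any record of
psychosis/bipolar disorder/mania/dementia) are applied patient-wide for
diagnoses and per-episode otherwise, each drop logged with one
machine-readable reason.

**Exposure model.** Registries record dispensations, not consumption. A
dispensation covers `supply_days` days; fills of the same drug merge into
one exposure interval when the coverage gap is at most a 30-day grace. A
drug trial must start inside the episode, last at least 28 days, and start
strictly more than 28 days after the previous *accepted* trial's
initiation ("previous treatment initiation" is read as the previous
accepted trial, since rejected candidates are not trials; a config flag
switches to any prior initiation). ECT/rTMS are exempt from gap and
duration rules; sessions at most 14 days apart collapse into one course =
one trial. Same-day ties resolve deterministically: procedures first, then
the longer exposure, then lexicographic ATC code. The quetiapine >100
mg/day floor is evaluated on the interval's initiating dispensation.

**Matching.** Controls are used without replacement across sets (the
published control count is consistent with episode-level uniqueness), and
cases are processed in seeded random order so control depletion cannot be
systematic. The age caliper is ±5 years at the case's index date.

**Index-date transfer.** The source design gives matched controls "the
same index date" as their case. Two readings are implemented:
`calendar` (literal; the default for descriptive profiling) and `offset`
(control index = control's episode start + the case's start-to-index
interval, guaranteed to fall inside the control episode by the duration
criterion). For *hazard estimation* the offset mode is the identifiable
design: the duration criterion guarantees a control's survival to its own
start + tti, so anchoring follow-up there leaves no immortal person-time,
whereas a calendar index can precede the guaranteed-survival horizon and
bias the hazard ratio upward. The package's parameter-recovery tests
therefore use offset mode; the mode used is recorded on the output.

**Censoring.** Follow-up runs from the index date to the first of
emigration, death, the first post-index record of an exclusion diagnosis,
or the administrative end of the study (default 2018-12-31). Self-harm
events qualify only from inpatient or psychiatric (specialised) outpatient
records. Cox models use Efron tie handling and a cluster-robust sandwich
variance with the patient as cluster. Month bins are 30-day windows
anchored at the index date; the "after" aggregate includes the index
month. Lost workdays are restricted to ages 20-64 and spells of at least
14 days, with spell days apportioned to the bins they overlap.

**Risk model.** The feature table takes MADRS-S from the latest structured
rating 1-14 days strictly before episode start (a rating on the start day
is not "before the start"); same-day duplicates resolve to the maximum
score. Lookback windows (12-month visits, 3-year sleep/anxiety/substance
flags) end the day before episode start. The outcome is TRD within 365
days, administratively censored at 365. Missing values are imputed by
chained-equations predictive mean matching (5 donors), conditioning on all
other candidates plus the event indicator and the Nelson-Aalen cumulative
hazard — the standard auxiliary pair for survival outcomes — with imputed
MADRS-S clipped to [0, 54]; with a single incomplete column the chain
converges in one pass. Per-imputation Cox fits are pooled by Rubin's
rules. "Approximating x% of the full model" is implemented as explained
variation (R²) of the reduced linear predictor regressed on the full
linear predictor — the standard step-down model approximation — because
the source does not name its metric; variables are removed backward while
the threshold (default 0.95) is maintained, and reduced coefficients are
re-estimated against the full linear predictor. Validation reports
Harrell's C (apparent and optimism-corrected via the refit-and-test
bootstrap) and decile calibration at 365 days. The nomogram assigns the
widest-spanning variable 0-100 points, scales the rest by |coefficient ×
range|, and maps total points to absolute risk through the baseline
cumulative hazard of an offset fit.

## What the generator emulates — and what it does not

The source material gives no generative model, so the simulator's
distributions are stand-ins chosen to give every pipeline stage signal to
detect, not estimates of the real registry:

* Episode starts are uniform over 2012-2017 inside a 2010-2018 extract;
  patients contribute 1-3 episodes separated by quiet gaps of 400+ days.
* First-trial delay and the trial 1→2 and 2→3 gaps are log-normal with
  medians 8, 165 and 197 days (the published medians), floored at 29 days
  so planted trials always satisfy the spacing rule.
* 11% of treated, fully eligible episodes are planted on a ≥3-trial TRD
  trajectory through a logistic model in MADRS-S severity, care setting,
  prior visits, sleep and anxiety flags and sex; the intercept is
  calibrated so the marginal planting rate equals `p_trd_track`.
* First-line treatment is 60% SSRI; later lines spread over SNRI, NaSSA,
  NDRI, TCA, add-ons and ECT/rTMS.
* Mortality is piecewise exponential at 8.7/1000 person-years, multiplied
  by `trd_mortality_hr` after the first planted index date. Death,
  emigration and the end of the window truncate all later events, and
  planted labels whose third trial is truncated away are demoted, keeping
  ground truth and emitted events exactly consistent.
* MADRS-S ratings are deleted missing-at-random through a logistic model
  in care setting and prior visit count, calibrated to a 95% marginal
  missingness rate.

The generator does **not** reproduce the real registry's summary
statistics (that is explicitly out of scope), its dispensation noise
(partial adherence, stockpiling), regional care patterns, or
non-MAR missingness. Passing the recovery tests therefore shows that the
pipeline's logic is correct under controlled conditions — not that its
estimates on real Stockholm data would match published values.

A note on truncation: the registry window right-censors long inter-trial
gaps (an episode starting in 2017 cannot show a 600-day switch), so naive
medians of observed gaps are biased low. Recovery tests for the planted
165-day median restrict to episodes with at least three years of potential
follow-up, where that bias is a few percent.

## Problem sizes used in the tests

Unit tests run on cohorts of a few hundred to a few thousand patients.
The acceptance-style checks use the sizes at which their properties are
sharp: 10,000 random small instances for the brute-force oracle
comparisons, 5,000 patients for exact planted-label recovery, 100 cohorts
of 20,000 patients for coverage of the planted mortality HR (plus 200
permutation replicates for null calibration), and ~10,000 episodes with 20
imputations for the missing-data bias check. These sizes are the package's
choices for statistically meaningful yet quick checks.

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(n_patients = 5000, seed = 1))
cl <- run_classification(co$tables)

# matched cohort and mortality contrast
mt <- match_episodes(cl$status, co$tables$demographics, seed = 1)
mm <- assign_index_dates(mt, cl$status, mode = "offset")
fit_survival(mm, co$tables)

# monthly profiles and sequences
monthly_mean_series(mm, co$tables, "outpatient_visits")$aggregates
sequence_paths(cl$trials[cl$trials$episode_id %in%
                           cl$status$episode_id[cl$status$is_trd], ])$n_paths

# prognostic risk score
ft <- build_features(cl$status, co$tables)
rmod <- trd_risk_model(ft, m = 20, n_boot = 100, seed = 1)
summary(rmod)
```

## Known limitations

* The exposure model (supply-day coverage plus grace) is an implementer's
  choice; the source is silent on how drug duration is computed.
* Control reuse policy, the index-transfer reading, and the episode-level
  (rather than patient-level) utilization means are documented decisions
  where the source is ambiguous; each has a flag or a stated default.
* The candidate-variable list of the risk model beyond the six named
  predictors is configurable; the shipped defaults add age, prior-episode
  count and a substance-use flag as stand-ins for the unpublished
  supplementary list.
* Bootstrap validation resamples episodes, not patients; with at most a
  few episodes per patient the difference is small, but correlated
  episodes slightly flatter the optimism estimate.
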