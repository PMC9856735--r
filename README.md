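# trdcohort

Computational phenotyping and outcome analysis of treatment-resistant
depression (TRD) in longitudinal health-registry data.

Routine-care registries never record "treatment resistant" directly. The
phenotype is constructed from dated event streams: an MDD episode opens at
an ICD-10 F32/F33 diagnosis and closes at the last depression-related event
followed by ≥365 event-free days; antidepressants (ATC N06A), qualifying
add-on drugs (aripiprazole, lithium, olanzapine, quetiapine >100 mg/day,
risperidone) and ECT/rTMS count as treatment trials when initiated within
the episode, more than 28 days after the previous trial initiation, with
≥28 days of exposure (interval criteria waived for ECT/rTMS); an episode
reaching a **third** valid trial is TRD, indexed at that trial's
initiation. `trdcohort` implements this construction plus the analyses that
sit on top of it, for epidemiologists working with EHR/claims-style event
tables:

* **Episodes and exclusions** — `build_episodes()`, `apply_exclusions()`
  (age ≥ 18, >12 months pre-start residency, no
  psychosis/bipolar/mania/dementia records), with a machine-readable
  exclusion log.
* **Trials and TRD** — `estimate_exposure()` (supply-day coverage with a
  30-day grace), `identify_trials()`, `classify_trd()`.
* **Matched cohort** — `match_episodes()`: up to 5 non-TRD episodes per TRD
  episode, exact on sex/SES/prior-episode count, age within ±5 years,
  antidepressant-treated, and lasting at least the case's start-to-index
  interval; `assign_index_dates()` transfers the index in `calendar` or
  `offset` mode.
* **Outcomes** — `cumulative_comorbidity_series()` and
  `monthly_mean_series()` (−12..+12 month profiles of comorbidity,
  outpatient visits, bed-days, lost workdays), `fit_survival()`
  (cluster-robust Cox for all-cause mortality and intentional self-harm,
  with person-years and rates per 1000), `km_episode_duration()`,
  `trial_interval_summary()`.
* **Sequences** — `classify_treatment()`, `sequence_paths()` (the table
  behind an alluvial plot of trial 1→2→3 treatment classes).
* **Prognosis** — `trd_risk_model()`: Cox risk score for TRD within one
  year of episode start, with chained-equations multiple imputation of the
  ~95%-missing MADRS-S rating, Rubin pooling, step-down approximation of
  the full model, bootstrap-validated Harrell C, calibration, and a
  nomogram (`export_nomogram()`).
* **Synthetic registry** — `simulate_cohort()` generates the seven event
  tables with planted ground truth (TRD labels and index dates, a planted
  mortality hazard ratio, true risk-score coefficients), so the whole
  pipeline is testable without access to real registry data.

In Cox notation, the survival contrast is
`h(t | TRD) = h0(t) · exp(β·TRD)` with robust (sandwich) standard errors
clustered on the patient, follow-up from the index date, censoring at
emigration, death, a first post-index exclusion diagnosis, or
administrative end of study. The risk model is
`h(t | x) = h0(t) · exp(x'β)` on time-to-TRD administratively censored at
365 days, fitted on each of *m* imputed data sets and pooled by Rubin's
rules; the published "final model approximating 95% of the full model" is
implemented as explained variation of the reduced linear predictor
regressed on the full one.

## Worked example

```r
library(trdcohort)

co <- simulate_cohort(sim_config(n_patients = 5000, seed = 1))
cl <- run_classification(co$tables)

mt <- match_episodes(cl$status, co$tables$demographics, seed = 1)
mm <- assign_index_dates(mt, cl$status, mode = "offset")
fit_survival(mm, co$tables)
```

```
Matched TRD cohort (primary mode, ratio <= 5)
  323 cases, 1474 controls (achieved ratio 4.56), 24 unmatched cases
Cox contrast, outcome: all-cause mortality
  HR 1.18 (95% CI 0.57-2.47), cluster-robust
     group events person_years rate_per_1000py
1:     TRD      9     955.0951        9.423145
2: non-TRD     32    4046.3628        7.908337
```

347 of 5084 kept episodes fulfil TRD criteria; 323 find at least one
eligible control. With only 41 deaths the interval estimate is wide — the
planted hazard ratio (1.23) is recovered tightly in the package's
100-replicate test at n = 20,000 patients. Inter-trial intervals on the
complete-capture subset (episodes with ≥3 years of potential follow-up):

```r
full_fu <- cl$status$start_date <= as.Date("2015-12-31")
trial_interval_summary(cl$trials[cl$trials$episode_id %in%
                                   cl$status$episode_id[full_fu], ],
                       cl$status[full_fu, ])
```

```
          interval     n median_days q1_days q3_days
1:  start_to_first  2458           8       3    22.0
2: first_to_second  1019         157      71   333.5
3: second_to_third   261         203      94   405.0
4:    start_to_trd   261         466     282   814.0
```

The medians track the generator's planted 8/165/197-day log-normal gaps.
The prognostic model:

```r
ft <- build_features(cl$status, co$tables)
rmod <- trd_risk_model(ft, m = 20, n_boot = 100, seed = 1)
rmod
```

```
TRD prognostic risk model
  2641 episodes, 63 TRD events within 365 days
  full model: 9 variables pooled over 20 imputations
  reduced model: 4 variables, 95.3% of the full model
  C index 0.732 apparent, 0.718 optimism-corrected (100 bootstraps)
```

MADRS-S (95% missing, imputed) is retained in the reduced model; the
reduced set approximates 95.3% of the full model's linear predictor, and
optimism correction moves the C index only slightly — the behaviour the
method is designed to exhibit when severity carries most of the signal.

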