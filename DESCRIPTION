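Package: trdcohort
Title: Computational Phenotyping and Outcome Analysis of
    Treatment-Resistant Depression in Health Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing major depressive disorder (MDD) episodes
    from longitudinal health-care event streams (diagnoses, drug
    dispensations, procedures, sick leave, symptom ratings), identifying
    antidepressant treatment trials and treatment-resistant depression (TRD)
    by rule-based criteria, assembling exact-matched TRD/non-TRD episode
    cohorts with shared index dates, profiling comorbidity, health-care
    resource utilization and lost workdays in monthly windows around the
    index date, fitting cluster-robust Cox models for mortality and
    self-harm, extracting treatment-sequence distributions, and building a
    prognostic Cox risk score for TRD with chained-equations multiple
    imputation, step-down model approximation, bootstrap validation and
    nomogram export. A synthetic registry generator with planted ground
    truth makes every pipeline stage testable without access to real
    registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival (>= 3.4),
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
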