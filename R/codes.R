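#' Default treatment class map
#'
#' Maps ATC codes and procedure labels to the treatment groups used when
#' summarising antidepressant sequences: SSRI, NaSSA, SNRI, NDRI, TCA,
#' add-on medication (aripiprazole, lithium, olanzapine, quetiapine above the
#' dose floor, risperidone), agomelatine, vortioxetine, other antidepressants,
#' and ECT/rTMS. The map is a plain data.frame and can be replaced or extended
#' by the user; [classify_treatment()] consumes it.
#'
#' @return data.frame with columns `code`, `class`, `label`.
#' @export
default_treatment_classes <- function() {
  d <- rbind(
    data.frame(code = c("N06AB03", "N06AB04", "N06AB05", "N06AB06", "N06AB10"),
               class = "SSRI",
               label = c("fluoxetine", "citalopram", "paroxetine", "sertraline",
                         "escitalopram")),
    data.frame(code = "N06AX11", class = "NaSSA", label = "mirtazapine"),
    data.frame(code = c("N06AX16", "N06AX21"), class = "SNRI",
               label = c("venlafaxine", "duloxetine")),
    data.frame(code = "N06AX12", class = "NDRI", label = "bupropion"),
    data.frame(code = c("N06AA04", "N06AA09", "N06AA10"), class = "TCA",
               label = c("clomipramine", "amitriptyline", "nortriptyline")),
    data.frame(code = "N06AX22", class = "agomelatine", label = "agomelatine"),
    data.frame(code = "N06AX26", class = "vortioxetine", label = "vortioxetine"),
    data.frame(code = c("N06AX03", "N06AX05", "N06AG02"), class = "other_AD",
               label = c("mianserin", "trazodone", "moclobemide")),
    data.frame(code = c("N05AX12", "N05AN01", "N05AH03", "N05AH04", "N05AX08"),
               class = "add_on",
               label = c("aripiprazole", "lithium", "olanzapine", "quetiapine",
                         "risperidone")),
    data.frame(code = c("ECT", "rTMS"), class = "ECT_rTMS",
               label = c("ECT", "rTMS"))
  )
  d$class <- as.character(d$class)
  d
}

#' Default depression-related event definition
#'
#' An MDD episode opens at an F32/F33 diagnosis and is extended by
#' depression-related events: F32/F33 diagnoses, antidepressant (ATC N06A)
#' dispensations, add-on dispensations, and ECT/rTMS/psychotherapy procedure
#' contacts. Whether psychotherapy alone extends an episode is controlled by
#' `include_psychotherapy` (default `TRUE`).
#'
#' @param include_psychotherapy should psychotherapy contacts extend episodes?
#' @return list of code sets consumed by [build_episodes()].
#' @export
default_episode_codes <- function(include_psychotherapy = TRUE) {
  procs <- c("ECT", "rTMS")
  if (include_psychotherapy) procs <- c(procs, "psychotherapy")
  list(
    diagnosis_prefixes = c("F32", "F33"),
    antidepressant_prefixes = "N06A",
    addon_codes = c("N05AX12", "N05AN01", "N05AH03", "N05AH04", "N05AX08"),
    procedures = procs
  )
}

#' Default exclusion diagnosis prefixes
#'
#' Records of psychosis, bipolar disorder, manic episode or dementia exclude a
#' patient's episodes from the unipolar MDD sample.
#'
#' @return character vector of ICD-10 prefixes.
#' @export
default_exclusion_codes <- function() {
  c("F20", "F21", "F22", "F23", "F24", "F25", "F28", "F29",  # psychosis
    "F30", "F31",                                            # mania / bipolar
    "F00", "F01", "F02", "F03", "G30")                       # dementia
}

#' Default psychiatric comorbidity code sets
#'
#' Condition groups used for the monthly cumulative-comorbidity profiles and
#' baseline prevalence tables.
#'
#' @return named list of ICD-10 prefix vectors.
#' @export
default_comorbidity_codes <- function() {
  list(
    anxiety        = "F41",
    stress         = "F43",
    sleep_disorder = c("G47", "F51"),
    substance_use  = c("F10", "F11", "F12", "F13", "F14", "F15", "F16", "F19"),
    ocd            = "F42",
    self_harm      = paste0("X", 60:84)
  )
}
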