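# Small in-code fixture builders for hand-crafted cohorts.

ts_mar <- function(day, hour = 10, min = 0) {
  sprintf("2021-03-%02dT%02d:%02d", day, hour, min)
}

adm_row <- function(id, age = 70, los = 10, admit = ts_mar(1, 8), sex = "male",
                    n_dx = 5, allergy = FALSE, excluded = "") {
  tibble::tibble(admission_id = id, age = age, sex = sex, admit_ts = admit,
                 discharge_ts = format_ts(parse_ts(admit) + los * 86400),
                 length_of_stay = los, n_diagnoses = n_dx,
                 allergy_history = allergy, allergy_list = "",
                 excluded_flags = excluded)
}

med_row <- function(id, name, class, start = ts_mar(2), stop = NA,
                    abrupt = FALSE, dose_reduced = FALSE) {
  tibble::tibble(admission_id = id, drug_name = name, drug_class = class,
                 start_ts = start, stop_ts = if (is.na(stop)) NA_character_ else stop,
                 abrupt_stop = abrupt, dose_reduced = dose_reduced)
}

lab_row <- function(id, analyte, value, ts = ts_mar(3)) {
  tibble::tibble(admission_id = id, analyte = analyte, value = value,
                 unit = unname(gtt_vocab()$units[analyte]), ts = ts)
}

ev_row <- function(id, code, ts = ts_mar(3), flags = "") {
  tibble::tibble(admission_id = id, code = code, ts = ts,
                 context_flags = flags)
}

ctx_row <- function(id, ...) {
  flags <- list(...)
  out <- tibble::tibble(admission_id = id)
  all_flags <- c("diabetes", "thyroid_dysfunction",
                 "gout_or_hyperuricemia_history", "dementia_or_parkinson",
                 "chronic_renal_failure", "hepatobiliary_pancreatic_disease",
                 "primary_muscle_disease", "peptic_ulcer_history",
                 "on_parenteral_nutrition")
  for (fl in all_flags) out[[fl]] <- isTRUE(flags[[fl]])
  out
}

toy_cohort <- function(admissions, meds = NULL, labs = NULL, events = NULL,
                       context = NULL) {
  suppressWarnings(gtt_cohort(admissions, meds, labs, events, context))
}

# one admission carrying the given rows; context via ... flags
one_adm_cohort <- function(meds = NULL, labs = NULL, events = NULL, ...,
                           los = 10) {
  toy_cohort(adm_row("P1", los = los), meds, labs, events, ctx_row("P1", ...))
}
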