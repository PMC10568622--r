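# Controlled vocabularies for the tabular EHR data model.

#' Controlled vocabularies used by the data model
#'
#' Named list of the code sets the validators and the trigger engine rely on:
#' drug classes, laboratory analytes with their fixed units, clinical event
#' codes, patient-context comorbidity flags, admission exclusion flags,
#' system-organ classes and onset-time bins.
#'
#' Units are fixed per analyte and validated, never converted: every
#' laboratory threshold in the default trigger registry is stated in exactly
#' one unit.
#'
#' @return named list of character vectors (`units` is a named vector keyed
#'   by analyte).
#' @export
gtt_vocab <- function() {
  list(
    sex = c("male", "female"),
    drug_class = c(
      "antibacterial", "anticoagulant", "hypoglycemic", "diuretic", "ACEI",
      "contrast_agent", "benzodiazepine", "digoxin_like", "PPI", "NSAID",
      "corticosteroid", "hypokalemic", "hyperkalemic", "hyponatremic",
      "sedative_hypnotic", "antiparkinson", "platelet_inhibitor", "SSRI",
      "other"
    ),
    analyte = names(.analyte_units),
    units = .analyte_units,
    event_code = c(
      "rash", "oversedation_fall", "delirium", "epilepsy",
      "cognitive_disorder", "edema", "hemorrhage", "dry_cough",
      "nausea_vomiting", "diarrhea", "myalgia", "myasthenia", "myositis",
      "dark_urine", "ecg_abnormal", "dizziness", "palpitation", "sweating",
      "malaise", "vision_abnormal", "epistaxis"
    ),
    event_context_flags = c("pre_existing_cough", "history_peptic_ulcer"),
    context_flags = c(
      "diabetes", "thyroid_dysfunction", "gout_or_hyperuricemia_history",
      "dementia_or_parkinson", "chronic_renal_failure",
      "hepatobiliary_pancreatic_disease", "primary_muscle_disease",
      "peptic_ulcer_history"
    ),
    excluded_flags = c("malignant_tumor", "organ_transplant", "palliative",
                       "icu_transfer"),
    organ_system = c(
      "gastrointestinal", "metabolic_nutritional", "skin_appendages",
      "cardiovascular_general", "hepatobiliary", "cns_pns",
      "heart_rate_rhythm", "platelet_bleeding_clotting", "autonomic",
      "respiratory", "body_general", "vision"
    ),
    onset_bins = c("<=5 h", "5 h-1 day", "1-2 days", "2-4 days", "4-8 days",
                   ">8 days", "prior_to_admission"),
    naranjo_categories = c("definite", "probable", "possible", "doubtful"),
    severity_descriptors = c(
      "mild_no_intervention", "minimal_local_noninvasive",
      "severe_or_hospitalization", "life_threatening", "death"
    )
  )
}

.analyte_units <- c(
  K = "mmol/L", Na = "mmol/L",
  glucose_fasting = "mmol/L", glucose_postprandial = "mmol/L",
  glucose_random = "mmol/L",
  ALT = "U/L", ALP = "U/L",
  creatinine = "umol/L", eGFR = "mL/min",
  PT = "s", APTT = "s", INR = "ratio",
  platelets = "10^9/L", TSH = "mIU/L", WBC = "10^9/L", CK = "U/L",
  hemoglobin = "g/L", uric_acid = "umol/L",
  systolic_bp = "mmHg", urine_output_rate = "mL/(kg.h)",
  drug_level_theophylline = "mg/L", drug_level_digoxin = "ng/mL",
  drug_level_vancomycin = "mg/L", drug_level_gentamicin = "mg/L",
  drug_level_carbamazepine = "mg/L"
)

analyte_unit <- function(analyte) unname(.analyte_units[analyte])
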