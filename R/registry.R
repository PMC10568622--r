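# Trigger registry: the 36 screening rules (17 laboratory, 10 treatment,
# 8 clinical-symptom, 1 intervention), their thresholds and context
# requirements, plus YAML round-trip and the engine configuration.

#' Engine configuration
#'
#' Policy knobs of the trigger engine, with defaults reproducing the primary
#' trigger list.
#'
#' @param drug_window_days a laboratory/symptom trigger with a named drug
#'   class requires a drug of that class active within this many days before
#'   the observation (default 7; most ADEs arise within 2 days of
#'   administration, 7 days is a conservative envelope).
#' @param counting_policy `"per_stay"` (default: at most one hit per
#'   admission and trigger, the conservative GTT reading) or
#'   `"per_occurrence"`.
#' @param i1_include_dose_reduction if `TRUE`, the abrupt-stop intervention
#'   trigger also fires on dose reductions (an optional extension of the
#'   primary list; default `FALSE`).
#' @param lookback_hours pre-admission window within which baseline
#'   laboratory values are accepted (default 48).
#' @return a `gtt_config` list.
#' @export
gtt_config <- function(drug_window_days = 7,
                       counting_policy = c("per_stay", "per_occurrence"),
                       i1_include_dose_reduction = FALSE,
                       lookback_hours = 48) {
  counting_policy <- match.arg(counting_policy)
  stopifnot(drug_window_days > 0, lookback_hours >= 0)
  structure(list(drug_window_days = drug_window_days,
                 counting_policy = counting_policy,
                 i1_include_dose_reduction = i1_include_dose_reduction,
                 lookback_hours = lookback_hours),
            class = "gtt_config")
}

new_trigger <- function(id, module, name, interpretation, params = list(),
                        requires_class = NULL, requires_name = NULL,
                        exclude_context = NULL) {
  structure(list(id = id, module = module, name = name,
                 interpretation = interpretation, params = params,
                 requires_class = requires_class,
                 requires_name = requires_name,
                 exclude_context = exclude_context),
            class = "gtt_trigger")
}

#' The default trigger registry
#'
#' Returns the 36 screening rules of the elderly-inpatient trigger list:
#' laboratory triggers L1-L17, treatment triggers T1-T10, clinical-symptom
#' triggers C1-C8 and the intervention trigger I1. Thresholds that are
#' hospital-adjustable (liver-enzyme upper limits of normal; the coagulation
#' cut-offs of L8) are parameters with documented defaults, not constants.
#'
#' @return named list of 36 trigger definitions, in registry order.
#' @export
default_trigger_registry <- function() {
  defs <- list(
    new_trigger("L1", "laboratory", "hypokalaemia",
                "serum potassium below threshold with a hypokalaemic drug in use",
                params = list(k_below = 3.0),
                requires_class = c("hypokalemic", "diuretic")),
    new_trigger("L2", "laboratory", "hyperkalaemia",
                "serum potassium above threshold (lower cut-off with reduced eGFR) with a hyperkalaemic drug in use",
                params = list(k_above = 6.0, k_above_renal = 5.5, egfr_below = 50),
                requires_class = "hyperkalemic"),
    new_trigger("L3", "laboratory", "hyponatraemia",
                "serum sodium below threshold with a hyponatraemic drug in use",
                params = list(na_below = 130),
                requires_class = "hyponatremic"),
    new_trigger("L4", "laboratory", "hypoglycaemia",
                "serum glucose below threshold (higher cut-off in diabetes) with a hypoglycaemic drug in use",
                params = list(glucose_below = 2.8, glucose_below_diabetic = 3.9),
                requires_class = "hypoglycemic"),
    new_trigger("L5", "laboratory", "hyperglycaemia",
                "fasting/postprandial glucose above threshold (non-diabetic) or glucose rising above the in-stay baseline (diabetic), with a hyperglycaemia-inducing or mismanaged hypoglycaemic drug",
                params = list(fasting_at_least = 7.0, postprandial_at_least = 7.8,
                              diabetic_rise_margin = 3.0),
                requires_class = c("hypoglycemic", "corticosteroid")),
    new_trigger("L6", "laboratory", "liver_injury",
                "ALT and ALP both at or above twice the upper limit of normal",
                params = list(alt_uln = 40, alp_uln = 150, uln_multiple = 2),
                exclude_context = c("on_parenteral_nutrition",
                                    "hepatobiliary_pancreatic_disease")),
    new_trigger("L7", "laboratory", "kidney_injury",
                "creatinine above twice the baseline value, or eGFR fallen by a quarter, or sustained oliguria; baseline is the lower of the admission value and the in-stay minimum",
                params = list(creatinine_fold = 2, egfr_drop_fraction = 0.25,
                              urine_below = 0.5, urine_min_hours = 12)),
    new_trigger("L8", "laboratory", "coagulation_disorder",
                "PT, APTT or INR above hospital-adjusted thresholds",
                params = list(pt_above = 12.1, aptt_above = 36.5, inr_above = 3.5)),
    new_trigger("L9", "laboratory", "thrombocytopenia",
                "platelet count below threshold",
                params = list(platelets_below = 50)),
    new_trigger("L10", "laboratory", "thyroid_dysfunction",
                "TSH outside the reference band in a patient without known thyroid dysfunction",
                params = list(tsh_at_least = 5.0, tsh_below = 0.3),
                exclude_context = "thyroid_dysfunction"),
    new_trigger("L11", "laboratory", "leukopenia",
                "white-cell count below threshold",
                params = list(wbc_below = 3)),
    new_trigger("L12", "laboratory", "myopathy",
                "creatine kinase above ten times the upper limit of normal, or a myopathy-type clinical event, in a patient without primary muscle disease",
                params = list(ck_uln = 200, ck_fold = 10,
                              event_codes = c("myalgia", "myasthenia",
                                              "myositis", "dark_urine")),
                exclude_context = "primary_muscle_disease"),
    new_trigger("L13", "laboratory", "erythropoietin_overshoot",
                "haemoglobin above threshold in chronic renal failure while on recombinant erythropoietin",
                params = list(hemoglobin_above = 120),
                requires_name = "erythropoietin"),
    new_trigger("L14", "laboratory", "ecg_abnormality",
                "electrocardiographic abnormality recorded",
                params = list(event_codes = "ecg_abnormal")),
    new_trigger("L15", "laboratory", "hyperuricaemia",
                "uric acid above threshold in a patient with no history of gout or hyperuricaemia",
                params = list(uric_acid_above = 428),
                exclude_context = "gout_or_hyperuricemia_history"),
    new_trigger("L16", "laboratory", "hypotension",
                "systolic pressure below threshold with a blood-pressure-lowering drug in use",
                params = list(systolic_below = 90),
                requires_class = c("ACEI", "diuretic")),
    new_trigger("L17", "laboratory", "drug_level_toxicity",
                "therapeutic drug level above the toxicity cut-off",
                params = list(theophylline_above = 20, digoxin_above = 2,
                              vancomycin_above = 20, gentamicin_above = 10,
                              carbamazepine_above = 13)),
    new_trigger("T1", "treatment", "vitamin_k",
                "vitamin K administered (reversal of vitamin K antagonists)",
                params = list(names = "vitamin_k")),
    new_trigger("T2", "treatment", "protamine",
                "protamine administered (reversal of heparin overdose)",
                params = list(names = "protamine")),
    new_trigger("T3", "treatment", "insulin_rescue_infusion",
                "glucose-insulin-potassium rescue infusion administered after drug-induced acidosis",
                params = list(names = c("insulin_rescue_infusion",
                                        "glucose_insulin_kcl_infusion"))),
    new_trigger("T4", "treatment", "allergy_rescue",
                "antihistamine or calcium gluconate given, or glucocorticoid combined with epinephrine, after drug allergy",
                params = list(names = c("diphenhydramine", "loratadine",
                                        "promethazine", "chlorpheniramine",
                                        "calcium_gluconate"),
                              combo_class = "corticosteroid",
                              combo_name = "epinephrine")),
    new_trigger("T5", "treatment", "hypertonic_glucose",
                "intravenous 50% glucose given after drug-induced hypoglycaemia",
                params = list(names = c("glucose_50_injection"))),
    new_trigger("T6", "treatment", "gut_flora_rescue",
                "live intestinal bacteria, oral vancomycin or oral metronidazole given to a patient on long-running antibiotics or proton-pump inhibitors",
                params = list(names = c("probiotic_live_bacteria",
                                        "oral_vancomycin", "oral_metronidazole")),
                requires_class = c("antibacterial", "PPI")),
    new_trigger("T7", "treatment", "hepatoprotective",
                "hepatoprotective drug administered",
                params = list(names = c("glutathione",
                                        "polyene_phosphatidylcholine",
                                        "magnesium_isoglycyrrhizinate"))),
    new_trigger("T8", "treatment", "flumazenil",
                "flumazenil administered (benzodiazepine overdose reversal)",
                params = list(names = "flumazenil")),
    new_trigger("T9", "treatment", "antifungal_mouthcare",
                "nystatin or sodium bicarbonate mouthcare for antibiotic/steroid-associated thrush",
                params = list(names = c("nystatin", "sodium_bicarbonate"))),
    new_trigger("T10", "treatment", "digoxin_toxicity_rescue",
                "phenytoin, atropine or lidocaine given against digoxin-poisoning arrhythmias",
                params = list(names = c("phenytoin", "atropine", "lidocaine"))),
    new_trigger("C1", "symptom", "rash",
                "rash (drug-induced skin allergy)",
                params = list(event_codes = "rash")),
    new_trigger("C2", "symptom", "oversedation_fall",
                "over-sedation or fall with an antihypertensive, sedative-hypnotic, antiparkinsonian or hypoglycaemic drug in use",
                params = list(event_codes = "oversedation_fall"),
                requires_class = c("ACEI", "diuretic", "sedative_hypnotic",
                                   "antiparkinson", "hypoglycemic")),
    new_trigger("C3", "symptom", "delirium",
                "delirium (drug-induced neurological disorder)",
                params = list(event_codes = "delirium")),
    new_trigger("C4", "symptom", "epilepsy",
                "epileptic seizure (drug-induced)",
                params = list(event_codes = "epilepsy")),
    new_trigger("C5", "symptom", "cognitive_disorder",
                "cognitive disorder in a patient without dementia, Parkinson's disease or other degenerative cognitive disease",
                params = list(event_codes = "cognitive_disorder"),
                exclude_context = "dementia_or_parkinson"),
    new_trigger("C6", "symptom", "edema",
                "oedema (drug-induced)",
                params = list(event_codes = "edema")),
    new_trigger("C7", "symptom", "hemorrhage",
                "haemorrhage on antithrombotic therapy, or on NSAIDs/corticosteroids with a peptic-ulcer history and no regular PPI cover",
                params = list(event_codes = "hemorrhage",
                              antithrombotic_classes = c("platelet_inhibitor",
                                                         "anticoagulant"),
                              ulcerogenic_classes = c("NSAID", "corticosteroid"))),
    new_trigger("C8", "symptom", "dry_cough",
                "new dry cough with an ACE inhibitor in use (patient not coughing before the medication)",
                params = list(event_codes = "dry_cough"),
                requires_class = "ACEI"),
    new_trigger("I1", "intervention", "abrupt_stop",
                "medication stopped abruptly, suggesting an ADE requiring adjustment",
                params = list())
  )
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  defs
}

#' Write a trigger registry to YAML
#' @param registry list of trigger definitions.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trigger_registry <- function(registry, path) {
  plain <- lapply(unname(registry), function(tr) {
    out <- unclass(tr)
    out[!vapply(out, is.null, logical(1))]
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Load a trigger registry from YAML
#'
#' Reads a registry written by [write_trigger_registry()] (the shipped
#' default lives at `system.file("extdata", "trigger_registry.yaml",
#' package = "gttade")`) and validates it: all ids unique, modules known,
#' numeric thresholds numeric.
#'
#' @param path YAML file.
#' @return named list of trigger definitions.
#' @export
load_trigger_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("registry file not found: %s", path))
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw, function(entry) {
    for (fld in c("id", "module", "name", "interpretation")) {
      if (is.null(entry[[fld]])) {
        abort(sprintf("registry configuration error: entry missing '%s'", fld))
      }
    }
    if (!entry$module %in% c("laboratory", "treatment", "symptom", "intervention")) {
      abort(sprintf("registry configuration error: unknown module '%s' (%s)",
                    entry$module, entry$id))
    }
    params <- entry$params %||% list()
    numeric_ok <- vapply(params, function(p) is.numeric(p) || is.character(p),
                         logical(1))
    if (length(params) && !all(numeric_ok)) {
      abort(sprintf("registry configuration error: malformed params in %s", entry$id))
    }
    new_trigger(entry$id, entry$module, entry$name, entry$interpretation,
                params = params,
                requires_class = unlist(entry$requires_class) %||% NULL,
                requires_name = unlist(entry$requires_name) %||% NULL,
                exclude_context = unlist(entry$exclude_context) %||% NULL)
  })
  ids <- vapply(defs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    abort("registry configuration error: duplicate trigger ids")
  }
  names(defs) <- ids
  defs
}
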