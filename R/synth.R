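# synth module: seeded synthetic-cohort generator. Emulates the reference
# cohort's marginals (age, length of stay, medication and diagnosis counts,
# antibacterial use, allergy history, sex) and plants trigger conditions and
# adjudicated ADEs with known ground truth, so the rule engine, adjudication
# and metrics can be exercised end to end without real patient data.
#
# Background (non-planted) laboratory values are drawn from ranges that
# never cross any registry threshold, so on a noise-free cohort the engine's
# hit set equals the plant list exactly.

.default_plant_positives <- c(
  L1 = 6, L2 = 3, L3 = 11, L4 = 13, L5 = 4, L6 = 12, L7 = 1, L8 = 3, L9 = 4,
  L10 = 9, L11 = 4, L12 = 3, L13 = 1, L14 = 2, L15 = 73, L16 = 4, L17 = 1,
  T1 = 0, T2 = 0, T3 = 7, T4 = 8, T5 = 4, T6 = 2, T7 = 29, T8 = 0, T9 = 0,
  T10 = 1, C1 = 13, C2 = 1, C3 = 1, C4 = 1, C5 = 0, C6 = 15, C7 = 13,
  C8 = 3, I1 = 29)

.default_detections <- c(
  L1 = 1, L4 = 2, L5 = 1, L6 = 3, L8 = 1, L14 = 2, L15 = 8, L16 = 3,
  L17 = 1, T4 = 7, T7 = 2, T10 = 1, C1 = 8, C3 = 1, C7 = 3, C8 = 2, I1 = 21)

.organ_entry_counts <- c(
  gastrointestinal = 17, metabolic_nutritional = 15, skin_appendages = 9,
  cardiovascular_general = 4, hepatobiliary = 3, cns_pns = 3,
  heart_rate_rhythm = 2, platelet_bleeding_clotting = 2, autonomic = 2,
  respiratory = 2, body_general = 1, vision = 1)

.organ_symptoms <- list(
  gastrointestinal = c("nausea/vomiting", "diarrhoea", "gastrointestinal haemorrhage"),
  metabolic_nutritional = c("hypokalaemia", "hypoglycaemia", "hyperglycaemia"),
  skin_appendages = c("rash", "dermatitis/pruritus", "erythema"),
  cardiovascular_general = c("hypotension", "electrocardiograph abnormal"),
  hepatobiliary = "hepatic function abnormal",
  cns_pns = "dizziness/headache",
  heart_rate_rhythm = "palpitation/QT increased",
  platelet_bleeding_clotting = "epistaxis/coagulation time increased",
  autonomic = "sweating increased",
  respiratory = "dry cough",
  body_general = "general malaise",
  vision = "vision abnormal")

#' Synthetic-cohort generator configuration
#'
#' Marginal distributions, planted-prevalence parameters and noise controls
#' of [generate_cohort()]. Truncated-normal marginals are moment-calibrated:
#' the generator solves for underlying normal parameters so that the
#' truncated distribution itself has the stated mean and SD.
#'
#' @param n_admissions number of admissions (default 480).
#' @param seed RNG seed.
#' @param age,los,medications,diagnoses lists `mean`, `sd`, `min`, `max`
#'   describing truncated-normal marginals (defaults: age 72.61 +/- 5.94 on
#'   \[65, 91\]; stay 8.95 +/- 4.57 days on \[2, 27\]; medications 18.26 +/-
#'   6.42 on \[5, 40\]; diagnoses 5.38 +/- 2.80 on \[1, 19\]).
#' @param antibacterial_hours duration marginal (lognormal moment-matched to
#'   mean 53.42, SD 103.24, truncated to \[3, 528\] h).
#' @param p_female,p_antibacterial,p_allergy Bernoulli marginals.
#' @param ade_log_or_per_medication per-medication log-odds of ADE (0.087).
#' @param ade_prevalence overall ADE patient fraction the intercept is
#'   calibrated to (0.1062).
#' @param plant_rates named per-admission plant probability per trigger id
#'   (defaults proportional to the reference per-trigger positive counts
#'   over 480 admissions).
#' @param noise_rate per-admission probability of one additional spurious
#'   planted trigger condition (recorded in the ground truth with
#'   `is_noise = TRUE`; default 0).
#' @param detect_prob probability an ADE is covered by at least one planted
#'   trigger.
#' @param multiplicity_probs probabilities of 1, 2, 3 ADEs per ADE patient.
#' @param severity_probs probabilities of CTCAE grades 1-3.
#' @param onset_probs probabilities over the onset bins (up to 5 h, 5 h-1
#'   day, 1-2 days, 2-4 days, 4-8 days, prior to admission).
#' @param organ_probs probabilities over system-organ classes.
#' @param secondary_organ_rate chance an ADE involves a second organ system.
#' @param medication_error_rate fraction of ADEs flagged medication errors.
#' @param definite_rate fraction of included ADEs adjudicated definite
#'   (remainder probable).
#' @param extra_candidate_rate rate of additional possible/doubtful
#'   candidate rows (exercise the causality filter; dropped downstream).
#' @param context_prevalence named comorbidity-flag prevalences.
#' @param year calendar year the admissions span.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_admissions = 480,
                         seed = 1,
                         age = list(mean = 72.61, sd = 5.94, min = 65, max = 91),
                         los = list(mean = 8.95, sd = 4.57, min = 2, max = 27),
                         medications = list(mean = 18.26, sd = 6.42, min = 5, max = 40),
                         diagnoses = list(mean = 5.38, sd = 2.80, min = 1, max = 19),
                         antibacterial_hours = list(mean = 53.42, sd = 103.24,
                                                    min = 3, max = 528),
                         p_female = 0.4562,
                         p_antibacterial = 0.3083,
                         p_allergy = 0.1438,
                         ade_log_or_per_medication = 0.087,
                         ade_prevalence = 0.1062,
                         plant_rates = .default_plant_positives / 480,
                         noise_rate = 0,
                         detect_prob = 52 / 56,
                         multiplicity_probs = c(47, 3, 1) / 51,
                         severity_probs = c(11, 42, 3) / 56,
                         onset_probs = c(7, 23, 12, 9, 2, 3) / 56,
                         organ_probs = .organ_entry_counts / 61,
                         secondary_organ_rate = 5 / 56,
                         medication_error_rate = 2 / 56,
                         definite_rate = 0.15,
                         extra_candidate_rate = 0.2,
                         context_prevalence = c(
                           diabetes = 0.30, thyroid_dysfunction = 0.10,
                           gout_or_hyperuricemia_history = 0.10,
                           dementia_or_parkinson = 0.08,
                           chronic_renal_failure = 0.08,
                           hepatobiliary_pancreatic_disease = 0.10,
                           primary_muscle_disease = 0.02,
                           peptic_ulcer_history = 0.08,
                           on_parenteral_nutrition = 0.05),
                         year = 2021) {
  cfg <- list(n_admissions = n_admissions, seed = seed, age = age, los = los,
              medications = medications, diagnoses = diagnoses,
              antibacterial_hours = antibacterial_hours,
              p_female = p_female, p_antibacterial = p_antibacterial,
              p_allergy = p_allergy,
              ade_log_or_per_medication = ade_log_or_per_medication,
              ade_prevalence = ade_prevalence,
              plant_rates = plant_rates, noise_rate = noise_rate,
              detect_prob = detect_prob,
              multiplicity_probs = multiplicity_probs,
              severity_probs = severity_probs, onset_probs = onset_probs,
              organ_probs = organ_probs,
              secondary_organ_rate = secondary_organ_rate,
              medication_error_rate = medication_error_rate,
              definite_rate = definite_rate,
              extra_candidate_rate = extra_candidate_rate,
              context_prevalence = context_prevalence, year = year)
  probs <- c(p_female, p_antibacterial, p_allergy, ade_prevalence,
             plant_rates, noise_rate, detect_prob, multiplicity_probs,
             severity_probs, onset_probs, organ_probs, secondary_organ_rate,
             medication_error_rate, definite_rate, context_prevalence)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("infeasible config: all probabilities/rates must lie in [0, 1]")
  }
  if (n_admissions < 1) abort("infeasible config: n_admissions must be >= 1")
  if (is.null(names(plant_rates)) ||
      !all(names(plant_rates) %in% names(.default_plant_positives))) {
    abort("plant_rates must be named by trigger id")
  }
  structure(cfg, class = "synth_config")
}

.background_formulary <- data.frame(
  drug_name = c("amlodipine", "atorvastatin", "metoprolol",
                "isosorbide_mononitrate", "amiodarone", "aspirin",
                "clopidogrel", "warfarin", "low_molecular_weight_heparin",
                "furosemide", "hydrochlorothiazide", "torasemide",
                "spironolactone", "indapamide", "insulin", "metformin",
                "glimepiride", "enalapril", "perindopril", "omeprazole",
                "pantoprazole", "celecoxib", "methylprednisolone",
                "diazepam", "estazolam", "zolpidem", "levodopa",
                "sertraline", "digoxin", "theophylline", "iodixanol",
                "calcium_carbonate", "potassium_chloride"),
  drug_class = c("other", "other", "other", "other", "other",
                 "platelet_inhibitor", "platelet_inhibitor", "anticoagulant",
                 "anticoagulant", "hypokalemic", "hypokalemic", "diuretic",
                 "hyperkalemic", "hyponatremic", "hypoglycemic",
                 "hypoglycemic", "hypoglycemic", "ACEI", "ACEI", "PPI",
                 "PPI", "NSAID", "corticosteroid", "benzodiazepine",
                 "benzodiazepine", "sedative_hypnotic", "antiparkinson",
                 "SSRI", "digoxin_like", "other", "contrast_agent", "other",
                 "hyperkalemic"))

.antibacterial_formulary <- c("cefoperazone_tazobactam", "levofloxacin",
                              "piperacillin_tazobactam", "ceftriaxone")

minute_floor <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

.na_ts <- as.POSIXct(NA_character_, tz = "UTC")

# calibrate the logistic intercept so the expected ADE-patient fraction over
# the (integer-rounded, truncated) medication-count marginal equals the
# target prevalence
calibrate_ade_intercept <- function(cfg) {
  med <- cfg$medications
  cal <- calibrate_truncnorm(med$mean, med$sd, med$min, med$max)
  grid <- seq(med$min, med$max)
  p <- pnorm(pmin(grid + 0.5, med$max), cal$mu, cal$sigma) -
    pnorm(pmax(grid - 0.5, med$min), cal$mu, cal$sigma)
  p <- p / sum(p)
  beta <- cfg$ade_log_or_per_medication
  f <- function(b0) sum(p * plogis(b0 + beta * grid)) - cfg$ade_prevalence
  uniroot(f, c(-20, 5), tol = 1e-10)$root
}

# --- plant machinery ---------------------------------------------------

# Returns med/lab/event rows realizing `trigger_id` on the admission, plus
# context-flag overrides needed so no exclusion clause blocks the hit.
plant_condition <- function(trigger_id, adm, ctx_row, bg_labs) {
  admit <- adm$admit_ts
  los <- adm$length_of_stay
  id <- adm$admission_id
  obs <- minute_floor(admit + runif(1, 0.3, max(0.4, los - 0.3)) * 86400)
  drug_start <- minute_floor(pmax(admit, obs - runif(1, 0.25, 2) * 86400))
  med <- function(name, class, start = drug_start, stop = NA, abrupt = FALSE) {
    data.frame(admission_id = id, drug_name = name, drug_class = class,
               start_ts = start,
               stop_ts = if (is.na(stop[1])) .na_ts else stop,
               abrupt_stop = abrupt, dose_reduced = FALSE)
  }
  lab <- function(analyte, value, ts = obs) {
    data.frame(admission_id = id, analyte = analyte, value = round(value, 2),
               unit = analyte_unit(analyte), ts = ts)
  }
  event <- function(code, flags = "") {
    data.frame(admission_id = id, code = code, ts = obs, context_flags = flags)
  }
  out <- list(meds = NULL, labs = NULL, events = NULL, ctx_set = NULL,
              suspect = NA_character_, ts = obs)
  add <- function(out, meds = NULL, labs = NULL, events = NULL,
                  ctx_set = NULL, suspect = NULL) {
    out$meds <- rbind(out$meds, meds)
    out$labs <- rbind(out$labs, labs)
    out$events <- rbind(out$events, events)
    out$ctx_set <- c(out$ctx_set, ctx_set)
    if (!is.null(suspect)) out$suspect <- suspect
    out
  }
  glu_base <- function() {
    g <- bg_labs$value[bg_labs$analyte %in% c("glucose_fasting",
                                              "glucose_postprandial",
                                              "glucose_random")]
    if (length(g)) min(g) else NA_real_
  }
  switch(trigger_id,
    L1 = add(out, med("furosemide", "hypokalemic"),
             lab("K", runif(1, 2.2, 2.9)), suspect = "furosemide"),
    L2 = add(out, med("spironolactone", "hyperkalemic"),
             lab("K", runif(1, 6.1, 7.2)), suspect = "spironolactone"),
    L3 = add(out, med("indapamide", "hyponatremic"),
             lab("Na", runif(1, 121, 129)), suspect = "indapamide"),
    L4 = add(out, med("insulin", "hypoglycemic"),
             lab("glucose_random",
                 if (isTRUE(ctx_row$diabetes)) runif(1, 3.0, 3.8)
                 else runif(1, 2.0, 2.7)),
             suspect = "insulin"),
    L5 = {
      if (isTRUE(ctx_row$diabetes)) {
        base <- glu_base()
        labs <- NULL
        if (is.na(base)) {
          base <- 5.0
          labs <- lab("glucose_random", base,
                      ts = minute_floor(admit + 0.15 * 86400))
        }
        labs <- rbind(labs, lab("glucose_random",
                                base + 3.0 + runif(1, 0.6, 3)))
        add(out, med("methylprednisolone", "corticosteroid"), labs,
            suspect = "methylprednisolone")
      } else {
        add(out, med("methylprednisolone", "corticosteroid"),
            lab("glucose_fasting", runif(1, 7.5, 11)),
            suspect = "methylprednisolone")
      }
    },
    L6 = add(out, labs = rbind(lab("ALT", runif(1, 85, 240)),
                               lab("ALP", runif(1, 310, 520))),
             ctx_set = c(on_parenteral_nutrition = FALSE,
                         hepatobiliary_pancreatic_disease = FALSE)),
    L7 = {
      base <- bg_labs$value[bg_labs$analyte == "creatinine"]
      labs <- NULL
      if (length(base) == 0) {
        b <- runif(1, 60, 90)
        labs <- lab("creatinine", b, ts = minute_floor(admit + 0.1 * 86400))
      } else b <- min(base)
      labs <- rbind(labs, lab("creatinine", b * runif(1, 2.05, 3)))
      add(out, labs = labs)
    },
    L8 = {
      pick <- sample(c("INR", "PT", "APTT"), 1)
      val <- switch(pick, INR = runif(1, 3.6, 6), PT = runif(1, 12.5, 20),
                    APTT = runif(1, 38, 60))
      add(out, med("warfarin", "anticoagulant"), lab(pick, val),
          suspect = "warfarin")
    },
    L9 = add(out, labs = lab("platelets", runif(1, 10, 45))),
    L10 = add(out, labs = lab("TSH", if (runif(1) < 0.5) runif(1, 5.5, 15)
                              else runif(1, 0.05, 0.25)),
              ctx_set = c(thyroid_dysfunction = FALSE)),
    L11 = add(out, labs = lab("WBC", runif(1, 1.0, 2.8))),
    L12 = add(out, labs = lab("CK", runif(1, 2100, 5000)),
              ctx_set = c(primary_muscle_disease = FALSE)),
    L13 = add(out, med("erythropoietin", "other"),
              lab("hemoglobin", runif(1, 125, 155)),
              ctx_set = c(chronic_renal_failure = TRUE),
              suspect = "erythropoietin"),
    L14 = add(out, events = event("ecg_abnormal")),
    L15 = add(out, labs = lab("uric_acid", runif(1, 440, 700)),
              ctx_set = c(gout_or_hyperuricemia_history = FALSE)),
    L16 = add(out, med("enalapril", "ACEI"),
              lab("systolic_bp", runif(1, 70, 88)), suspect = "enalapril"),
    L17 = {
      if (runif(1) < 0.7) {
        add(out, med("digoxin", "digoxin_like"),
            lab("drug_level_digoxin", runif(1, 2.2, 4)), suspect = "digoxin")
      } else {
        add(out, med("theophylline", "other"),
            lab("drug_level_theophylline", runif(1, 21, 35)),
            suspect = "theophylline")
      }
    },
    T1 = add(out, med("vitamin_k", "other"), suspect = "vitamin_k"),
    T2 = add(out, med("protamine", "other"), suspect = "protamine"),
    T3 = add(out, med("glucose_insulin_kcl_infusion", "other"),
             suspect = "glucose_insulin_kcl_infusion"),
    T4 = {
      pick <- sample(c("antihistamine", "calcium", "combo"), 1)
      meds <- switch(pick,
        antihistamine = med(sample(c("diphenhydramine", "loratadine"), 1), "other"),
        calcium = med("calcium_gluconate", "other"),
        combo = rbind(med("methylprednisolone", "corticosteroid"),
                      med("epinephrine", "other")))
      add(out, meds, suspect = meds$drug_name[1])
    },
    T5 = add(out, med("glucose_50_injection", "other"),
             suspect = "glucose_50_injection"),
    T6 = add(out, rbind(
      med("omeprazole", "PPI",
          start = minute_floor(pmax(admit, drug_start - 2 * 86400))),
      med("probiotic_live_bacteria", "other")),
      suspect = "probiotic_live_bacteria"),
    T7 = add(out, med("glutathione", "other"), suspect = "glutathione"),
    T8 = add(out, med("flumazenil", "other"), suspect = "flumazenil"),
    T9 = add(out, med(sample(c("nystatin", "sodium_bicarbonate"), 1), "other")),
    T10 = add(out, med(sample(c("phenytoin", "atropine", "lidocaine"), 1),
                       "other")),
    C1 = add(out, events = event("rash")),
    C2 = add(out, med("zolpidem", "sedative_hypnotic"),
             events = event("oversedation_fall"), suspect = "zolpidem"),
    C3 = add(out, events = event("delirium")),
    C4 = add(out, events = event("epilepsy")),
    C5 = add(out, events = event("cognitive_disorder"),
             ctx_set = c(dementia_or_parkinson = FALSE)),
    C6 = add(out, events = event("edema")),
    C7 = add(out, med("aspirin", "platelet_inhibitor"),
             events = event("hemorrhage"), suspect = "aspirin"),
    C8 = add(out, med("enalapril", "ACEI"), events = event("dry_cough"),
             suspect = "enalapril"),
    I1 = add(out, med("amlodipine", "other",
                      start = minute_floor(admit + runif(1, 0, 0.2) * 86400),
                      stop = obs, abrupt = TRUE),
             suspect = "amlodipine"),
    abort(sprintf("no plant recipe for trigger '%s'", trigger_id))
  )
}

# background lab panel with values inside never-triggering ranges
background_labs <- function(adm) {
  id <- adm$admission_id
  admit <- adm$admit_ts
  los <- adm$length_of_stay
  an <- list(); vals <- list(); tss <- list()
  emit <- function(analyte, values, ts = NULL) {
    k <- length(values)
    if (is.null(ts)) {
      ts <- minute_floor(admit + sort(runif(k, 0.05, max(0.2, los - 0.05))) * 86400)
    }
    an[[length(an) + 1]] <<- rep(analyte, k)
    vals[[length(vals) + 1]] <<- round(values, 2)
    tss[[length(tss) + 1]] <<- as.numeric(ts)
  }
  k <- function() sample(1:3, 1)
  emit("K", runif(k(), 3.6, 5.2))
  emit("Na", runif(k(), 136, 144))
  emit("glucose_random", runif(k(), 4.6, 5.8))
  # all background glucose stays below 6.0: a planted diabetic hypoglycaemia
  # (value >= 3.0) must not drag the L5 rise threshold under any background
  if (runif(1) < 0.5) emit("glucose_fasting", runif(k(), 4.6, 5.8))
  cr_base <- runif(1, 55, 95)
  n_cr <- k()
  emit("creatinine", c(cr_base, cr_base + runif(max(0, n_cr - 1), 0, 38)))
  emit("ALT", runif(k(), 10, 38))
  emit("ALP", runif(k(), 45, 140))
  emit("platelets", runif(k(), 160, 320))
  emit("WBC", runif(k(), 4, 9.5))
  emit("hemoglobin", runif(k(), 100, 150))
  if (runif(1) < 0.6) emit("uric_acid", runif(k(), 180, 420))
  if (runif(1) < 0.6) emit("systolic_bp", runif(k(), 100, 145))
  if (runif(1) < 0.3) emit("TSH", runif(k(), 0.6, 4.4))
  if (runif(1) < 0.3) emit("CK", runif(k(), 40, 180))
  if (runif(1) < 0.3) {
    emit("PT", runif(k(), 10, 12))
    emit("APTT", runif(k(), 28, 36))
    emit("INR", runif(k(), 0.9, 1.4))
  }
  if (runif(1) < 0.3) {
    eg_base <- runif(1, 60, 100)
    n_eg <- k()
    emit("eGFR", eg_base * c(1, runif(max(0, n_eg - 1), 0.88, 1)))
  }
  analyte <- unlist(an)
  data.frame(admission_id = id, analyte = analyte,
             value = unlist(vals), unit = analyte_unit(analyte),
             ts = as.POSIXct(unlist(tss), origin = "1970-01-01", tz = "UTC"))
}

sample_onset_delta_hours <- function(bin) {
  switch(bin,
         "<=5 h" = runif(1, 0.25, 5),
         "5 h-1 day" = runif(1, 5.02, 24),
         "1-2 days" = runif(1, 24.02, 48),
         "2-4 days" = runif(1, 48.02, 96),
         "4-8 days" = runif(1, 96.02, 192))
}

naranjo_answer_set <- function(category) {
  a <- rep("unknown", 10)
  if (category == "definite") a[1:6] <- c("yes", "yes", "yes", "yes", "no", "no")
  if (category == "probable") a[c(1, 2, 3, 5)] <- c("yes", "yes", "yes", "no")
  if (category == "possible") a[2] <- "yes"
  if (category == "doubtful") a[5] <- "yes"
  if (runif(1) < 0.5 && category != "doubtful") a[7] <- "yes"
  a
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws demographics, stays, medications, laboratory series, clinical
#' events and comorbidity context from the configured marginals; plants
#' trigger-positive conditions per trigger at the configured rates (each
#' plant inserts the exact rows the engine predicate needs, and context
#' flags are set so no exclusion clause blocks it); and plants adjudicated
#' ADEs whose probability follows a logistic model in the medication count,
#' with the intercept calibrated numerically to the target prevalence.
#' Identical seeds yield identical output.
#'
#' @param config a [synth_config()].
#' @param verify re-evaluate every planted condition with the engine and
#'   stop if any fails to fire (default `TRUE`).
#' @return list with `cohort` (a `gtt_cohort`), `ground_truth` (list:
#'   `plants` tibble of planted trigger conditions with `is_noise`, `ades`
#'   tibble of planted ADEs, `ade_intercept`), and `adjudications` (tibble
#'   in `adjudications.csv` shape, including possible/doubtful candidates).
#' @export
generate_cohort <- function(config = synth_config(), verify = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_admissions
  voc <- gtt_vocab()

  cal_age <- calibrate_truncnorm(config$age$mean, config$age$sd,
                                 config$age$min, config$age$max)
  cal_los <- calibrate_truncnorm(config$los$mean, config$los$sd,
                                 config$los$min, config$los$max)
  cal_med <- calibrate_truncnorm(config$medications$mean, config$medications$sd,
                                 config$medications$min, config$medications$max)
  cal_dx <- calibrate_truncnorm(config$diagnoses$mean, config$diagnoses$sd,
                                config$diagnoses$min, config$diagnoses$max)

  ids <- sprintf("A%04d", seq_len(n))
  month <- sample(rep(1:12, length.out = n))
  admit <- minute_floor(ISOdatetime(config$year, month,
                                    sample(1:28, n, replace = TRUE),
                                    sample(8:18, n, replace = TRUE),
                                    sample(0:59, n, replace = TRUE),
                                    0, tz = "UTC"))
  los <- pmin(pmax(round(rtruncnorm(n, cal_los$mu, cal_los$sigma,
                                    config$los$min, config$los$max)),
                   config$los$min), config$los$max)
  admissions <- tibble(
    admission_id = ids,
    age = as.integer(round(rtruncnorm(n, cal_age$mu, cal_age$sigma,
                                      config$age$min, config$age$max))),
    sex = ifelse(runif(n) < config$p_female, "female", "male"),
    admit_ts = admit,
    discharge_ts = admit + los * 86400,
    length_of_stay = as.numeric(los),
    n_diagnoses = as.integer(pmin(pmax(round(
      rtruncnorm(n, cal_dx$mu, cal_dx$sigma, config$diagnoses$min,
                 config$diagnoses$max)), config$diagnoses$min),
      config$diagnoses$max)),
    allergy_history = runif(n) < config$p_allergy,
    allergy_list = "",
    excluded_flags = "")
  admissions$allergy_list[admissions$allergy_history] <-
    sample(c("penicillin", "sulfonamides", "penicillin;sulfonamides"),
           sum(admissions$allergy_history), replace = TRUE,
           prob = c(0.5, 0.35, 0.15))

  ctx <- empty_context(ids)
  for (fl in names(config$context_prevalence)) {
    ctx[[fl]] <- runif(n) < config$context_prevalence[[fl]]
  }

  n_meds_target <- as.integer(pmin(pmax(round(
    rtruncnorm(n, cal_med$mu, cal_med$sigma, config$medications$min,
               config$medications$max)), config$medications$min),
    config$medications$max))
  antibacterial <- runif(n) < config$p_antibacterial

  # --- choose plants ---------------------------------------------------
  rates <- config$plant_rates
  plant_mat <- matrix(runif(n * length(rates)), nrow = n) <
    matrix(rates, nrow = n, ncol = length(rates), byrow = TRUE)
  colnames(plant_mat) <- names(rates)
  noise_pick <- runif(n) < config$noise_rate
  for (i in which(noise_pick)) {
    cand <- sample(names(rates), 1, prob = pmax(rates, 1e-6))
    if (!plant_mat[i, cand]) plant_mat[i, cand] <- NA  # NA marks noise plant
  }

  # --- ADE outcome and coverage plants ---------------------------------
  b0 <- calibrate_ade_intercept(config)
  p_ade <- plogis(b0 + config$ade_log_or_per_medication * n_meds_target)
  has_ade <- runif(n) < p_ade
  det_w <- .default_detections
  extra_links <- vector("list", n)
  ade_plan <- vector("list", n)
  for (i in which(has_ade)) {
    k <- sample(1:3, 1, prob = config$multiplicity_probs)
    planted_here <- names(rates)[which(!is.na(plant_mat[i, ]) & plant_mat[i, ])]
    plans <- list()
    for (j in seq_len(k)) {
      detected <- runif(1) < config$detect_prob
      links <- character()
      if (detected) {
        n_links <- 1 + rbinom(1, 2, 0.144)
        pool <- planted_here
        if (length(pool) < n_links) {
          need <- n_links - length(pool)
          newt <- sample(names(det_w), need, replace = TRUE, prob = det_w)
          newt <- setdiff(unique(newt), pool)
          for (tr in newt) {
            if (is.na(plant_mat[i, tr]) || !plant_mat[i, tr]) {
              plant_mat[i, tr] <- TRUE
            }
          }
          pool <- union(pool, newt)
          planted_here <- union(planted_here, newt)
        }
        links <- sample(pool, min(n_links, length(pool)))
      }
      plans[[j]] <- links
    }
    ade_plan[[i]] <- plans
  }

  # --- realize plants --------------------------------------------------
  labs_l <- vector("list", n)
  meds_l <- vector("list", n)
  events_l <- vector("list", n)
  plants_l <- list()
  plant_info <- list()  # per admission: trigger -> list(suspect, ts, drug_start)
  for (i in seq_len(n)) {
    adm <- admissions[i, ]
    bg <- background_labs(adm)
    labs_l[[i]] <- bg
    trigs <- colnames(plant_mat)[which(plant_mat[i, ] | is.na(plant_mat[i, ]))]
    info_i <- list()
    for (tr in trigs) {
      pl <- plant_condition(tr, adm, as.list(ctx[i, ]), bg)
      labs_l[[i]] <- bind_rows(labs_l[[i]], pl$labs)
      meds_l[[i]] <- bind_rows(meds_l[[i]], pl$meds)
      events_l[[i]] <- bind_rows(events_l[[i]], pl$events)
      if (!is.null(pl$ctx_set)) {
        for (fl in names(pl$ctx_set)) ctx[[fl]][i] <- pl$ctx_set[[fl]]
      }
      info_i[[tr]] <- list(suspect = pl$suspect, ts = pl$ts,
                           drug_start = if (!is.null(pl$meds)) pl$meds$start_ts[1]
                                        else NA)
      plants_l[[length(plants_l) + 1]] <- data.frame(
        admission_id = adm$admission_id, trigger_id = tr, ts = pl$ts,
        is_noise = is.na(plant_mat[i, tr]))
    }
    plant_info[[i]] <- info_i

    # background medications: top up to the target count
    n_planted <- if (is.null(meds_l[[i]])) 0L else nrow(meds_l[[i]])
    n_bg <- max(0L, n_meds_target[i] - n_planted - as.integer(antibacterial[i]))
    if (n_bg > 0) {
      pick <- .background_formulary[
        sample(nrow(.background_formulary), n_bg, replace = TRUE), ]
      start <- minute_floor(adm$admit_ts +
                              runif(n_bg, 0, max(0.3, adm$length_of_stay - 0.5)) * 86400)
      dur <- runif(n_bg, 0.5, adm$length_of_stay) * 86400
      stop <- minute_floor(pmin(start + dur, adm$discharge_ts))
      stop[runif(n_bg) < 0.3] <- NA
      meds_l[[i]] <- bind_rows(meds_l[[i]], data.frame(
        admission_id = adm$admission_id, drug_name = pick$drug_name,
        drug_class = pick$drug_class, start_ts = start, stop_ts = stop,
        abrupt_stop = FALSE, dose_reduced = FALSE))
    }
    if (antibacterial[i]) {
      ab <- config$antibacterial_hours
      sdlog <- sqrt(log(1 + (ab$sd / ab$mean)^2))
      mulog <- log(ab$mean) - sdlog^2 / 2
      hours <- min(max(exp(rnorm(1, mulog, sdlog)), ab$min), ab$max)
      start <- minute_floor(adm$admit_ts +
                              runif(1, 0, max(0.2, adm$length_of_stay / 2)) * 86400)
      meds_l[[i]] <- bind_rows(meds_l[[i]], data.frame(
        admission_id = adm$admission_id,
        drug_name = sample(.antibacterial_formulary, 1),
        drug_class = "antibacterial", start_ts = start,
        stop_ts = minute_floor(start + hours * 3600),
        abrupt_stop = FALSE, dose_reduced = FALSE))
    }
  }

  # --- realize ADEs ----------------------------------------------------
  onset_bins <- c("<=5 h", "5 h-1 day", "1-2 days", "2-4 days", "4-8 days",
                  "prior_to_admission")
  ades_l <- list()
  ade_no <- 0L
  for (i in which(has_ade)) {
    adm <- admissions[i, ]
    info_i <- plant_info[[i]]
    meds_i <- meds_l[[i]]
    for (links in ade_plan[[i]]) {
      ade_no <- ade_no + 1L
      bin <- sample(onset_bins, 1, prob = config$onset_probs)
      suspect <- NA_character_
      admin_ts <- NULL
      if (length(links) > 0) {
        li <- info_i[[links[1]]]
        if (!is.na(li$suspect)) {
          suspect <- li$suspect
          admin_ts <- li$drug_start
        }
      }
      if (is.na(suspect)) {
        cand <- meds_i[!meds_i$drug_class %in% "antibacterial", , drop = FALSE]
        if (nrow(cand) == 0) cand <- meds_i
        pick <- cand[sample(nrow(cand), 1), ]
        suspect <- pick$drug_name
        admin_ts <- pick$start_ts
      }
      if (bin == "prior_to_admission") {
        onset_ts <- minute_floor(adm$admit_ts - runif(1, 1, 5) * 86400)
        admin_ts <- minute_floor(onset_ts - runif(1, 5, 48) * 3600)
      } else {
        if (is.null(admin_ts) || is.na(admin_ts)) {
          admin_ts <- minute_floor(adm$admit_ts + runif(1, 0, 0.5) * 86400)
        }
        avail <- hours_between(adm$discharge_ts, admin_ts)
        delta <- sample_onset_delta_hours(bin)
        if (delta > avail) {
          fit <- c("<=5 h", "5 h-1 day", "1-2 days", "2-4 days", "4-8 days")
          lower <- c(0, 5, 24, 48, 96)
          ok <- fit[lower < avail]
          if (length(ok) > 0) {
            bin <- ok[length(ok)]
            delta <- min(sample_onset_delta_hours(bin), avail - 0.1)
          }
        }
        onset_ts <- minute_floor(admin_ts + delta * 3600)
      }
      organ <- sample(names(config$organ_probs), 1, prob = config$organ_probs)
      organs <- organ
      if (runif(1) < config$secondary_organ_rate) {
        organs <- c(organ, sample(setdiff(names(config$organ_probs), organ), 1))
      }
      grade <- sample(1:3, 1, prob = config$severity_probs)
      category <- if (runif(1) < config$definite_rate) "definite" else "probable"
      ans <- naranjo_answer_set(category)
      ades_l[[length(ades_l) + 1]] <- tibble(
        ade_id = sprintf("ADE%04d", ade_no),
        admission_id = adm$admission_id,
        suspect_drugs = suspect,
        admin_ts = admin_ts, onset_ts = onset_ts,
        organ_system = paste(organs, collapse = ";"),
        clinical_symptom = sample(.organ_symptoms[[organ]], 1),
        severity_descriptor = voc$severity_descriptors[grade],
        !!!setNames(as.list(ans), paste0("q", 1:10)),
        linked_triggers = paste(links, collapse = ";"),
        medication_error = runif(1) < config$medication_error_rate,
        naranjo_category_truth = category,
        ctcae_grade_truth = grade)
    }
  }
  ades <- if (length(ades_l)) bind_rows(ades_l) else NULL

  # extra possible/doubtful candidates to exercise the causality filter
  n_extra <- rbinom(1, max(1L, ade_no), config$extra_candidate_rate)
  extra_l <- list()
  for (j in seq_len(n_extra)) {
    i <- sample(n, 1)
    adm <- admissions[i, ]
    meds_i <- meds_l[[i]]
    if (is.null(meds_i) || nrow(meds_i) == 0) next
    pick <- meds_i[sample(nrow(meds_i), 1), ]
    category <- sample(c("possible", "doubtful"), 1)
    ans <- naranjo_answer_set(category)
    admin_ts <- pick$start_ts
    onset_ts <- minute_floor(admin_ts + runif(1, 1, 24) * 3600)
    organ <- sample(names(config$organ_probs), 1, prob = config$organ_probs)
    extra_l[[j]] <- tibble(
      ade_id = sprintf("CAND%04d", j),
      admission_id = adm$admission_id,
      suspect_drugs = pick$drug_name,
      admin_ts = admin_ts, onset_ts = onset_ts,
      organ_system = organ,
      clinical_symptom = sample(.organ_symptoms[[organ]], 1),
      severity_descriptor = "mild_no_intervention",
      !!!setNames(as.list(ans), paste0("q", 1:10)),
      linked_triggers = "",
      medication_error = FALSE,
      naranjo_category_truth = category,
      ctcae_grade_truth = 1L)
  }
  adjudications <- bind_rows(c(list(ades), extra_l))

  all_events <- bind_rows(events_l)
  all_meds <- bind_rows(meds_l)
  cohort <- gtt_cohort(admissions,
                       medications = if (nrow(all_meds)) all_meds,
                       labs = bind_rows(labs_l),
                       events = if (nrow(all_events)) all_events,
                       context = ctx,
                       on_reject = "error")
  plants <- if (length(plants_l)) bind_rows(plants_l) else
    tibble(admission_id = character(), trigger_id = character(),
           ts = parse_ts(character()), is_noise = logical())
  plants <- arrange(plants, .data$admission_id, .data$trigger_id)

  if (verify && nrow(plants) > 0) {
    verify_plants(cohort, plants)
  }

  list(cohort = cohort,
       ground_truth = list(plants = plants,
                           ades = ades %||% tibble(),
                           ade_intercept = b0),
       adjudications = adjudications)
}

# generation-time self-check: every planted condition must fire
verify_plants <- function(cohort, plants) {
  registry <- default_trigger_registry()
  config <- gtt_config()
  ids <- unique(plants$admission_id)
  sub <- cohort
  for (nm in .cohort_tables) sub[[nm]] <- sub[[nm]][sub[[nm]]$admission_id %in% ids, ]
  hits <- evaluate_cohort(sub, registry, config)
  want <- paste(plants$admission_id, plants$trigger_id)
  got <- paste(hits$admission_id, hits$trigger_id)
  miss <- setdiff(want, got)
  if (length(miss) > 0) {
    abort(sprintf("generator self-check failed: planted condition(s) did not fire: %s",
                  paste(head(miss, 5), collapse = "; ")))
  }
  invisible(TRUE)
}

#' Summary-level study-counts fixture
#'
#' The printed summary counts of the 480-admission development cohort as a
#' counts-only input for the metrics layer: per-trigger positives and
#' ADE-detection pairs, the rate-panel counts (patient-days from 480
#' admissions x 8.95 mean days of stay), onset-time, severity, system-organ
#' and multiplicity counts, and review totals. Feeding these to
#' [ppv_table()], [rate_panel()] and [distribution_tables_from_counts()]
#' reproduces every headline rate without simulating patient rows.
#'
#' The system-organ counts total 61 entries over 56 ADEs (an ADE may involve
#' more than one entry); the metabolic/nutritional total is reconciled to 15
#' so the entries sum to the published total (its printed sub-counts do not;
#' see the methods vignette).
#'
#' @return named list of counts and count tables.
#' @export
study_counts_fixture <- function() {
  list(
    trigger_counts = tibble(
      trigger_id = names(.default_plant_positives),
      positives = as.integer(.default_plant_positives),
      detections = as.integer(ifelse(
        is.na(.default_detections[names(.default_plant_positives)]), 0L,
        .default_detections[names(.default_plant_positives)]))),
    n_admissions = 480L,
    n_patients_with_ade = 51L,
    n_ades = 56L,
    mean_los_days = 8.95,
    patient_days = 480 * 8.95,
    n_patients_with_trigger = 232L,
    n_triggers = 36L,
    n_ades_undetected = 4L,
    n_ades_during_stay = 53L,
    onset_counts = tibble(
      onset_bin = c("<=5 h", "5 h-1 day", "1-2 days", "2-4 days", "4-8 days",
                    "prior_to_admission"),
      n = c(7L, 23L, 12L, 9L, 2L, 3L)),
    severity_counts = tibble(ctcae_grade = 1:3, n = c(11L, 42L, 3L)),
    organ_counts = tibble(
      organ_system = names(.organ_entry_counts),
      n = as.integer(.organ_entry_counts)),
    multiplicity_counts = tibble(n_ades_per_patient = 1:3,
                                 n_patients = c(47L, 3L, 1L)),
    sample_size_inputs = list(P = 0.10, Z = 1.96, delta = 0.03)
  )
}
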