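# Brute-force trigger oracle: an independent re-implementation of all 36
# screening rules as plain per-row loops with literal thresholds. Used only
# to cross-check the engine; shares no code with it.

oracle_hits <- function(cohort, window_days = 7) {
  win <- window_days * 86400
  out <- list()
  add <- function(id, tr) out[[length(out) + 1]] <<- c(id, tr)

  for (i in seq_len(nrow(cohort$admissions))) {
    id <- cohort$admissions$admission_id[i]
    meds <- cohort$medications[cohort$medications$admission_id == id, ]
    labs <- cohort$labs[cohort$labs$admission_id == id, ]
    evs <- cohort$events[cohort$events$admission_id == id, ]
    ctx <- as.list(cohort$context[cohort$context$admission_id == id, ])

    active <- function(t, classes = NULL, names = NULL) {
      if (nrow(meds) == 0) return(FALSE)
      for (j in seq_len(nrow(meds))) {
        match <- (!is.null(classes) && meds$drug_class[j] %in% classes) ||
          (!is.null(names) && meds$drug_name[j] %in% names)
        if (!match) next
        if (meds$start_ts[j] <= t &&
            (is.na(meds$stop_ts[j]) || meds$stop_ts[j] > t - win)) return(TRUE)
      }
      FALSE
    }
    lv <- function(a) {
      x <- labs[labs$analyte %in% a, ]
      x[order(x$ts), ]
    }
    has_med <- function(names) any(meds$drug_name %in% names)

    # --- laboratory ---
    K <- lv("K")
    for (j in seq_len(nrow(K))) {
      if (K$value[j] < 3.0 && active(K$ts[j], c("hypokalemic", "diuretic")))
        add(id, "L1")
      if (active(K$ts[j], "hyperkalemic")) {
        if (K$value[j] > 6) add(id, "L2")
        else if (K$value[j] > 5.5) {
          eg <- lv("eGFR")
          prior <- eg$value[eg$ts <= K$ts[j]]
          if (length(prior) && prior[length(prior)] < 50) add(id, "L2")
        }
      }
    }
    Na <- lv("Na")
    for (j in seq_len(nrow(Na))) {
      if (Na$value[j] < 130 && active(Na$ts[j], "hyponatremic")) add(id, "L3")
    }
    glu <- lv(c("glucose_fasting", "glucose_postprandial", "glucose_random"))
    cut4 <- if (isTRUE(ctx$diabetes)) 3.9 else 2.8
    for (j in seq_len(nrow(glu))) {
      if (glu$value[j] < cut4 && active(glu$ts[j], "hypoglycemic")) add(id, "L4")
    }
    if (!isTRUE(ctx$diabetes)) {
      for (j in seq_len(nrow(glu))) {
        hi <- (glu$analyte[j] == "glucose_fasting" && glu$value[j] >= 7.0) ||
          (glu$analyte[j] == "glucose_postprandial" && glu$value[j] >= 7.8)
        if (hi && active(glu$ts[j], c("hypoglycemic", "corticosteroid")))
          add(id, "L5")
      }
    } else if (nrow(glu) >= 2) {
      base <- min(glu$value)
      for (j in seq_len(nrow(glu))) {
        if (glu$value[j] > base + 3.0 &&
            active(glu$ts[j], c("hypoglycemic", "corticosteroid"))) add(id, "L5")
      }
    }
    if (!isTRUE(ctx$on_parenteral_nutrition) &&
        !isTRUE(ctx$hepatobiliary_pancreatic_disease)) {
      if (any(lv("ALT")$value >= 80) && any(lv("ALP")$value >= 300)) add(id, "L6")
    }
    cr <- lv("creatinine")
    if (nrow(cr) >= 2 && any(cr$value > 2 * min(cr$value))) add(id, "L7")
    eg <- lv("eGFR")
    if (nrow(eg) >= 2 && any(eg$value[-1] <= 0.75 * eg$value[1])) add(id, "L7")
    uo <- lv("urine_output_rate")
    if (nrow(uo) >= 2) {
      for (j in 2:nrow(uo)) {
        k <- j
        while (k >= 1 && uo$value[k] < 0.5) k <- k - 1
        if (k < j - 1 &&
            as.numeric(difftime(uo$ts[j], uo$ts[k + 1], units = "hours")) > 12)
          add(id, "L7")
      }
    }
    if (any(lv("PT")$value > 12.1) || any(lv("APTT")$value > 36.5) ||
        any(lv("INR")$value > 3.5)) add(id, "L8")
    if (any(lv("platelets")$value < 50)) add(id, "L9")
    if (!isTRUE(ctx$thyroid_dysfunction)) {
      tsh <- lv("TSH")$value
      if (any(tsh >= 5.0) || any(tsh < 0.3)) add(id, "L10")
    }
    if (any(lv("WBC")$value < 3)) add(id, "L11")
    if (!isTRUE(ctx$primary_muscle_disease)) {
      if (any(lv("CK")$value > 2000) ||
          any(evs$code %in% c("myalgia", "myasthenia", "myositis", "dark_urine")))
        add(id, "L12")
    }
    if (isTRUE(ctx$chronic_renal_failure)) {
      hb <- lv("hemoglobin")
      for (j in seq_len(nrow(hb))) {
        if (hb$value[j] > 120 && active(hb$ts[j], names = "erythropoietin"))
          add(id, "L13")
      }
    }
    if (any(evs$code == "ecg_abnormal")) add(id, "L14")
    if (!isTRUE(ctx$gout_or_hyperuricemia_history) &&
        any(lv("uric_acid")$value > 428)) add(id, "L15")
    sbp <- lv("systolic_bp")
    for (j in seq_len(nrow(sbp))) {
      if (sbp$value[j] < 90 && active(sbp$ts[j], c("ACEI", "diuretic")))
        add(id, "L16")
    }
    tox <- c(drug_level_theophylline = 20, drug_level_digoxin = 2,
             drug_level_vancomycin = 20, drug_level_gentamicin = 10,
             drug_level_carbamazepine = 13)
    for (a in names(tox)) {
      if (any(lv(a)$value > tox[[a]])) add(id, "L17")
    }

    # --- treatments ---
    if (has_med("vitamin_k")) add(id, "T1")
    if (has_med("protamine")) add(id, "T2")
    if (has_med(c("insulin_rescue_infusion", "glucose_insulin_kcl_infusion")))
      add(id, "T3")
    if (has_med(c("diphenhydramine", "loratadine", "promethazine",
                  "chlorpheniramine", "calcium_gluconate"))) add(id, "T4")
    if (any(meds$drug_class == "corticosteroid") && has_med("epinephrine"))
      add(id, "T4")
    if (has_med("glucose_50_injection")) add(id, "T5")
    t6 <- meds[meds$drug_name %in% c("probiotic_live_bacteria",
                                     "oral_vancomycin", "oral_metronidazole"), ]
    for (j in seq_len(nrow(t6))) {
      if (active(t6$start_ts[j], c("antibacterial", "PPI"))) add(id, "T6")
    }
    if (has_med(c("glutathione", "polyene_phosphatidylcholine",
                  "magnesium_isoglycyrrhizinate"))) add(id, "T7")
    if (has_med("flumazenil")) add(id, "T8")
    if (has_med(c("nystatin", "sodium_bicarbonate"))) add(id, "T9")
    if (has_med(c("phenytoin", "atropine", "lidocaine"))) add(id, "T10")

    # --- symptoms ---
    if (any(evs$code == "rash")) add(id, "C1")
    for (j in which(evs$code == "oversedation_fall")) {
      if (active(evs$ts[j], c("ACEI", "diuretic", "sedative_hypnotic",
                              "antiparkinson", "hypoglycemic"))) add(id, "C2")
    }
    if (any(evs$code == "delirium")) add(id, "C3")
    if (any(evs$code == "epilepsy")) add(id, "C4")
    if (!isTRUE(ctx$dementia_or_parkinson) &&
        any(evs$code == "cognitive_disorder")) add(id, "C5")
    if (any(evs$code == "edema")) add(id, "C6")
    for (j in which(evs$code == "hemorrhage")) {
      t <- evs$ts[j]
      c1 <- active(t, c("platelet_inhibitor", "anticoagulant"))
      c2 <- isTRUE(ctx$peptic_ulcer_history) &&
        active(t, c("NSAID", "corticosteroid")) && !active(t, "PPI")
      if (c1 || c2) add(id, "C7")
    }
    for (j in which(evs$code == "dry_cough")) {
      flags <- strsplit(evs$context_flags[j], ";")[[1]]
      if (!"pre_existing_cough" %in% flags && active(evs$ts[j], "ACEI"))
        add(id, "C8")
    }

    # --- intervention ---
    if (any(meds$abrupt_stop)) add(id, "I1")
  }
  if (length(out) == 0) {
    return(data.frame(admission_id = character(), trigger_id = character()))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("admission_id", "trigger_id")
  df <- unique(df)
  df[order(df$admission_id, df$trigger_id), , drop = FALSE]
}

hit_pairs <- function(hits) {
  df <- unique(data.frame(admission_id = hits$admission_id,
                          trigger_id = hits$trigger_id,
                          stringsAsFactors = FALSE))
  df[order(df$admission_id, df$trigger_id), , drop = FALSE]
}
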