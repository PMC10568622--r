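registry <- default_trigger_registry()

expect_fires <- function(cohort, trigger_id, n = 1) {
  hits <- evaluate_trigger(registry[[trigger_id]], cohort)
  expect_equal(nrow(hits), n,
               info = sprintf("%s expected %d hit(s)", trigger_id, n))
}

test_that("registry has all 36 rules exactly once, and the shipped YAML matches", {
  ids <- names(registry)
  expect_length(ids, 36)
  expect_setequal(ids, c(paste0("L", 1:17), paste0("T", 1:10),
                         paste0("C", 1:8), "I1"))
  modules <- table(vapply(registry, `[[`, character(1), "module"))
  expect_equal(modules[["laboratory"]], 17)
  expect_equal(modules[["treatment"]], 10)
  expect_equal(modules[["symptom"]], 8)
  expect_equal(modules[["intervention"]], 1)
  shipped <- load_trigger_registry(
    system.file("extdata", "trigger_registry.yaml", package = "gttade"))
  expect_equal(lapply(shipped, function(x) lapply(unclass(x), unlist)),
               lapply(registry, function(x) lapply(unclass(x), unlist)))
})

test_that("laboratory triggers fire on their thresholds with drug context", {
  # hypokalaemia: strict < 3.0 and a hypokalaemic-class drug active
  co <- one_adm_cohort(meds = med_row("P1", "furosemide", "hypokalemic"),
                       labs = lab_row("P1", "K", 2.8))
  expect_fires(co, "L1", 1)
  expect_fires(one_adm_cohort(meds = med_row("P1", "furosemide", "hypokalemic"),
                              labs = lab_row("P1", "K", 3.0)), "L1", 0)
  # no context drug -> no hit even with the abnormal value
  expect_fires(one_adm_cohort(labs = lab_row("P1", "K", 2.8)), "L1", 0)
  # drug started after the observation is not context
  expect_fires(one_adm_cohort(
    meds = med_row("P1", "furosemide", "hypokalemic", start = ts_mar(5)),
    labs = lab_row("P1", "K", 2.8, ts = ts_mar(3))), "L1", 0)

  # hyperkalaemia: the renal clause needs the reduced eGFR
  expect_fires(one_adm_cohort(
    meds = med_row("P1", "spironolactone", "hyperkalemic"),
    labs = dplyr::bind_rows(lab_row("P1", "K", 5.7, ts = ts_mar(4)),
                            lab_row("P1", "eGFR", 45, ts = ts_mar(3)))),
    "L2", 1)
  expect_fires(one_adm_cohort(
    meds = med_row("P1", "spironolactone", "hyperkalemic"),
    labs = dplyr::bind_rows(lab_row("P1", "K", 5.7, ts = ts_mar(4)),
                            lab_row("P1", "eGFR", 70, ts = ts_mar(3)))),
    "L2", 0)

  # hypoglycaemia cut-off depends on diabetes status
  meds <- med_row("P1", "insulin", "hypoglycemic")
  lab <- lab_row("P1", "glucose_random", 3.5)
  expect_fires(toy_cohort(adm_row("P1"), meds, lab, NULL,
                          ctx_row("P1", diabetes = TRUE)), "L4", 1)
  expect_fires(toy_cohort(adm_row("P1"), meds, lab, NULL, ctx_row("P1")),
               "L4", 0)

  # liver injury needs BOTH enzymes at >= 2x ULN and no excluding context
  alt_alp <- dplyr::bind_rows(lab_row("P1", "ALT", 90),
                              lab_row("P1", "ALP", 310))
  expect_fires(one_adm_cohort(labs = alt_alp), "L6", 1)
  expect_fires(one_adm_cohort(labs = lab_row("P1", "ALT", 90)), "L6", 0)
  expect_fires(toy_cohort(adm_row("P1"), NULL, alt_alp, NULL,
                          ctx_row("P1", hepatobiliary_pancreatic_disease = TRUE)),
               "L6", 0)

  # kidney injury: baseline is the in-stay minimum when no admission value
  expect_fires(one_adm_cohort(labs = dplyr::bind_rows(
    lab_row("P1", "creatinine", 80, ts = ts_mar(2)),
    lab_row("P1", "creatinine", 170, ts = ts_mar(6)))), "L7", 1)
  expect_fires(one_adm_cohort(labs = dplyr::bind_rows(
    lab_row("P1", "creatinine", 80, ts = ts_mar(2)),
    lab_row("P1", "creatinine", 155, ts = ts_mar(6)))), "L7", 0)

  # uric acid: history of gout/hyperuricaemia excludes the hit
  expect_fires(one_adm_cohort(labs = lab_row("P1", "uric_acid", 500)), "L15", 1)
  expect_fires(toy_cohort(adm_row("P1"), NULL, lab_row("P1", "uric_acid", 500),
                          NULL,
                          ctx_row("P1", gout_or_hyperuricemia_history = TRUE)),
               "L15", 0)

  # drug-level toxicity
  expect_fires(one_adm_cohort(labs = lab_row("P1", "drug_level_digoxin", 2.5)),
               "L17", 1)
  expect_fires(one_adm_cohort(labs = lab_row("P1", "drug_level_digoxin", 2.0)),
               "L17", 0)
})

test_that("treatment triggers fire on antidote administration", {
  expect_fires(one_adm_cohort(meds = med_row("P1", "vitamin_k", "other")),
               "T1", 1)
  # allergy rescue: antihistamine alone, or glucocorticoid + epinephrine
  expect_fires(one_adm_cohort(meds = med_row("P1", "loratadine", "other")),
               "T4", 1)
  expect_fires(one_adm_cohort(
    meds = dplyr::bind_rows(
      med_row("P1", "methylprednisolone", "corticosteroid"),
      med_row("P1", "epinephrine", "other"))), "T4", 1)
  expect_fires(one_adm_cohort(
    meds = med_row("P1", "methylprednisolone", "corticosteroid")), "T4", 0)
  # gut-flora rescue needs the antibiotic/PPI history
  expect_fires(one_adm_cohort(
    meds = dplyr::bind_rows(
      med_row("P1", "omeprazole", "PPI", start = ts_mar(1, 9)),
      med_row("P1", "probiotic_live_bacteria", "other", start = ts_mar(4)))),
    "T6", 1)
  expect_fires(one_adm_cohort(
    meds = med_row("P1", "probiotic_live_bacteria", "other")), "T6", 0)
})

test_that("symptom triggers respect drug context and history exclusions", {
  # haemorrhage clause 1: antithrombotic active
  expect_fires(one_adm_cohort(meds = med_row("P1", "aspirin", "platelet_inhibitor"),
                              events = ev_row("P1", "hemorrhage")), "C7", 1)
  expect_fires(one_adm_cohort(events = ev_row("P1", "hemorrhage")), "C7", 0)
  # clause 2: ulcer history + NSAID, blocked by regular PPI cover
  ulcer_nsaid <- function(ppi) {
    meds <- med_row("P1", "celecoxib", "NSAID")
    if (ppi) meds <- dplyr::bind_rows(meds, med_row("P1", "omeprazole", "PPI"))
    toy_cohort(adm_row("P1"), meds, NULL, ev_row("P1", "hemorrhage"),
               ctx_row("P1", peptic_ulcer_history = TRUE))
  }
  expect_fires(ulcer_nsaid(ppi = FALSE), "C7", 1)
  expect_fires(ulcer_nsaid(ppi = TRUE), "C7", 0)
  # dry cough: pre-existing cough excludes; needs an ACE inhibitor
  expect_fires(one_adm_cohort(meds = med_row("P1", "enalapril", "ACEI"),
                              events = ev_row("P1", "dry_cough")), "C8", 1)
  expect_fires(one_adm_cohort(
    meds = med_row("P1", "enalapril", "ACEI"),
    events = ev_row("P1", "dry_cough", flags = "pre_existing_cough")), "C8", 0)
  # cognitive disorder is not a trigger in degenerative disease
  expect_fires(toy_cohort(adm_row("P1"), NULL, NULL,
                          ev_row("P1", "cognitive_disorder"),
                          ctx_row("P1", dementia_or_parkinson = TRUE)), "C5", 0)
  expect_fires(one_adm_cohort(events = ev_row("P1", "cognitive_disorder")),
               "C5", 1)
})

test_that("abrupt-stop trigger fires on the flag; dose reduction only when enabled", {
  co <- one_adm_cohort(meds = med_row("P1", "amlodipine", "other",
                                      stop = ts_mar(5), abrupt = TRUE))
  expect_fires(co, "I1", 1)
  co2 <- one_adm_cohort(meds = med_row("P1", "amlodipine", "other",
                                       stop = ts_mar(5), dose_reduced = TRUE))
  expect_fires(co2, "I1", 0)
  hits <- evaluate_trigger(registry[["I1"]], co2,
                           gtt_config(i1_include_dose_reduction = TRUE))
  expect_equal(nrow(hits), 1)
})

test_that("degenerate cohorts produce empty hit tables", {
  empty <- suppressWarnings(gtt_cohort(adm_row("P1")[0, ]))
  expect_equal(nrow(evaluate_cohort(empty)), 0)
  quiet <- one_adm_cohort(meds = med_row("P1", "atorvastatin", "other"),
                          labs = dplyr::bind_rows(lab_row("P1", "K", 4.2),
                                                  lab_row("P1", "Na", 139)))
  expect_equal(nrow(evaluate_cohort(quiet)), 0)
})

test_that("counting policy caps hits per admission and trigger; per-occurrence keeps all", {
  co <- one_adm_cohort(
    meds = med_row("P1", "furosemide", "hypokalemic"),
    labs = dplyr::bind_rows(lab_row("P1", "K", 2.8, ts = ts_mar(3)),
                            lab_row("P1", "K", 2.6, ts = ts_mar(5))))
  per_stay <- evaluate_cohort(co)
  expect_equal(nrow(per_stay), 1)
  expect_equal(per_stay$ts, parse_ts(ts_mar(3)))  # earliest observation kept
  per_occ <- evaluate_cohort(co, config = gtt_config(counting_policy = "per_occurrence"))
  expect_equal(nrow(per_occ), 2)
})

test_that("activation summary counts per trigger and fired triggers", {
  co <- one_adm_cohort(meds = med_row("P1", "furosemide", "hypokalemic"),
                       labs = lab_row("P1", "K", 2.8))
  hits <- evaluate_cohort(co)
  s <- trigger_activation_summary(hits)
  expect_equal(sum(s$per_trigger$positives), nrow(hits))
  expect_equal(s$n_triggers_fired, 1)
  expect_equal(s$per_trigger$positives[s$per_trigger$trigger_id == "L1"], 1)
  s0 <- trigger_activation_summary(hits[0, ])
  expect_equal(s0$n_triggers_fired, 0)
  expect_equal(nrow(s0$per_trigger), 36)
})

test_that("threshold monotonicity: tightening a cut-off never adds hits", {
  g <- generate_cohort(synth_config(n_admissions = 120, seed = 3),
                       verify = FALSE)
  # "value < cut" rule: lowering the cut-off can only lose hits
  counts_l1 <- vapply(c(3.5, 3.0, 2.5, 2.0), function(cut) {
    defn <- registry[["L1"]]
    defn$params$k_below <- cut
    nrow(evaluate_trigger(defn, g$cohort))
  }, numeric(1))
  expect_true(all(diff(counts_l1) <= 0))
  # "value > cut" rule: raising the cut-off can only lose hits
  counts_l15 <- vapply(c(380, 428, 500, 600), function(cut) {
    defn <- registry[["L15"]]
    defn$params$uric_acid_above <- cut
    nrow(evaluate_trigger(defn, g$cohort))
  }, numeric(1))
  expect_true(all(diff(counts_l15) <= 0))
})

test_that("adding an exclusion flag never increases a patient's hits", {
  g <- generate_cohort(synth_config(n_admissions = 80, seed = 5),
                       verify = FALSE)
  base_hits <- evaluate_cohort(g$cohort)
  flagged <- g$cohort
  for (fl in c("gout_or_hyperuricemia_history", "thyroid_dysfunction",
               "primary_muscle_disease", "hepatobiliary_pancreatic_disease",
               "dementia_or_parkinson")) {
    flagged$context[[fl]] <- TRUE
  }
  flag_hits <- evaluate_cohort(flagged)
  expect_lte(nrow(flag_hits), nrow(base_hits))
  per_adm_base <- table(factor(base_hits$admission_id,
                               g$cohort$admissions$admission_id))
  per_adm_flag <- table(factor(flag_hits$admission_id,
                               g$cohort$admissions$admission_id))
  expect_true(all(per_adm_flag <= per_adm_base))
})

test_that("engine agrees with the brute-force oracle on small cohorts", {
  for (seed in c(2, 13, 27, 41)) {
    g <- generate_cohort(synth_config(n_admissions = 20, seed = seed,
                                      noise_rate = 0.2), verify = FALSE)
    engine <- hit_pairs(evaluate_cohort(g$cohort))
    oracle <- oracle_hits(g$cohort)
    expect_equal(engine, oracle, ignore_attr = TRUE,
                 info = sprintf("seed %d", seed))
  }
})

test_that("evaluation is deterministic", {
  g <- generate_cohort(synth_config(n_admissions = 60, seed = 9),
                       verify = FALSE)
  expect_identical(evaluate_cohort(g$cohort), evaluate_cohort(g$cohort))
})
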