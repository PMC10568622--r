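# triggers module: the rule engine. One predicate per registry entry,
# evaluated per admission over its labs / medications / events / context.
#
# Every predicate returns the set of observations satisfying the rule; the
# counting policy (default: at most one hit per admission and trigger)
# is applied afterwards in evaluate_cohort()/evaluate_trigger().

empty_hits <- function() {
  tibble(admission_id = character(), trigger_id = character(),
         ts = parse_ts(character()), evidence = character())
}

hit_rows <- function(ts, evidence) {
  if (length(ts) == 0) return(NULL)
  tibble(ts = ts, evidence = evidence)
}

# Is a drug of one of `classes` (or named `names`) active in the window
# [t - window_days, t]? Active = started at or before t and not stopped
# before the window opens (half-open [start, stop)).
drug_context_ok <- function(meds, ts, classes = NULL, names = NULL,
                            window_days = 7) {
  if (is.null(classes) && is.null(names)) return(rep(TRUE, length(ts)))
  if (nrow(meds) == 0 || length(ts) == 0) return(rep(FALSE, length(ts)))
  match_drug <- rep(FALSE, nrow(meds))
  if (!is.null(classes)) match_drug <- match_drug | meds$drug_class %in% classes
  if (!is.null(names)) match_drug <- match_drug | meds$drug_name %in% tolower(names)
  m <- meds[match_drug, , drop = FALSE]
  if (nrow(m) == 0) return(rep(FALSE, length(ts)))
  vapply(ts, function(t) {
    win <- t - window_days * 86400
    any(m$start_ts <= t & (is.na(m$stop_ts) | m$stop_ts > win))
  }, logical(1))
}

ctx_flag <- function(slice, flag) isTRUE(slice$ctx[[flag]])

lab_series <- function(slice, analytes) {
  lb <- slice$labs[slice$labs$analyte %in% analytes, , drop = FALSE]
  lb[order(lb$ts), , drop = FALSE]
}

lab_evidence <- function(lb) {
  sprintf("lab %s=%g %s @ %s", lb$analyte, lb$value, lb$unit, format_ts(lb$ts))
}

event_evidence <- function(ev) {
  sprintf("event %s @ %s", ev$code, format_ts(ev$ts))
}

med_evidence <- function(m) {
  sprintf("medication %s (%s) started %s", m$drug_name, m$drug_class,
          format_ts(m$start_ts))
}

# Generic: lab values satisfying `sel` (logical fn of the lab frame), gated
# by the trigger's drug-context requirement.
lab_threshold_hits <- function(slice, defn, analytes, sel) {
  lb <- lab_series(slice, analytes)
  if (nrow(lb) == 0) return(NULL)
  lb <- lb[sel(lb), , drop = FALSE]
  if (nrow(lb) == 0) return(NULL)
  ok <- drug_context_ok(slice$meds, lb$ts, defn$requires_class,
                        defn$requires_name, slice$config$drug_window_days)
  lb <- lb[ok, , drop = FALSE]
  hit_rows(lb$ts, lab_evidence(lb))
}

# Generic: clinical events with one of `codes`, drug-context gated, minus
# events carrying an excluding context flag.
event_hits <- function(slice, defn, codes, exclude_event_flags = NULL) {
  ev <- slice$events[slice$events$code %in% codes, , drop = FALSE]
  if (nrow(ev) == 0) return(NULL)
  if (!is.null(exclude_event_flags)) {
    flagged <- vapply(split_semi(ev$context_flags),
                      function(v) any(v %in% exclude_event_flags), logical(1))
    ev <- ev[!flagged, , drop = FALSE]
  }
  if (nrow(ev) == 0) return(NULL)
  ok <- drug_context_ok(slice$meds, ev$ts, defn$requires_class,
                        defn$requires_name, slice$config$drug_window_days)
  ev <- ev[ok, , drop = FALSE]
  hit_rows(ev$ts, event_evidence(ev))
}

# Generic: treatment trigger fires on administration of one of the named
# drugs within the stay.
treatment_hits <- function(slice, defn, names) {
  m <- slice$meds[slice$meds$drug_name %in% tolower(names), , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  if (!is.null(defn$requires_class)) {
    ok <- drug_context_ok(slice$meds, m$start_ts, defn$requires_class, NULL,
                          slice$config$drug_window_days)
    m <- m[ok, , drop = FALSE]
  }
  hit_rows(m$start_ts, med_evidence(m))
}

excluded_by_context <- function(slice, defn) {
  !is.null(defn$exclude_context) &&
    any(vapply(defn$exclude_context, function(fl) ctx_flag(slice, fl),
               logical(1)))
}

# most recent value of `analyte` at or before each t (NA when none)
latest_value_at <- function(slice, analyte, ts) {
  lb <- lab_series(slice, analyte)
  vapply(ts, function(t) {
    prior <- lb$value[lb$ts <= t]
    if (length(prior)) prior[length(prior)] else NA_real_
  }, numeric(1))
}

.trigger_predicates <- list(
  L1 = function(slice, defn) {
    lab_threshold_hits(slice, defn, "K",
                       function(lb) lb$value < defn$params$k_below)
  },
  L2 = function(slice, defn) {
    p <- defn$params
    lab_threshold_hits(slice, defn, "K", function(lb) {
      egfr <- latest_value_at(slice, "eGFR", lb$ts)
      lb$value > p$k_above |
        (lb$value > p$k_above_renal & !is.na(egfr) & egfr < p$egfr_below)
    })
  },
  L3 = function(slice, defn) {
    lab_threshold_hits(slice, defn, "Na",
                       function(lb) lb$value < defn$params$na_below)
  },
  L4 = function(slice, defn) {
    cut <- if (ctx_flag(slice, "diabetes")) defn$params$glucose_below_diabetic
           else defn$params$glucose_below
    lab_threshold_hits(slice, defn,
                       c("glucose_fasting", "glucose_postprandial",
                         "glucose_random"),
                       function(lb) lb$value < cut)
  },
  L5 = function(slice, defn) {
    p <- defn$params
    if (!ctx_flag(slice, "diabetes")) {
      lab_threshold_hits(slice, defn,
                         c("glucose_fasting", "glucose_postprandial"),
                         function(lb) {
        (lb$analyte == "glucose_fasting" & lb$value >= p$fasting_at_least) |
          (lb$analyte == "glucose_postprandial" &
             lb$value >= p$postprandial_at_least)
      })
    } else {
      # "higher than in the past": exceeds the admission-period minimum by a
      # configurable margin (interpretation; see vignette)
      glu <- lab_series(slice, c("glucose_fasting", "glucose_postprandial",
                                 "glucose_random"))
      if (nrow(glu) < 2) return(NULL)
      base <- min(glu$value)
      lab_threshold_hits(slice, defn,
                         c("glucose_fasting", "glucose_postprandial",
                           "glucose_random"),
                         function(lb) lb$value > base + p$diabetic_rise_margin)
    }
  },
  L6 = function(slice, defn) {
    if (excluded_by_context(slice, defn)) return(NULL)
    p <- defn$params
    alt <- lab_series(slice, "ALT")
    alp <- lab_series(slice, "ALP")
    alt_hi <- alt[alt$value >= p$uln_multiple * p$alt_uln, , drop = FALSE]
    alp_hi <- alp[alp$value >= p$uln_multiple * p$alp_uln, , drop = FALSE]
    if (nrow(alt_hi) == 0 || nrow(alp_hi) == 0) return(NULL)
    ts <- max(alt_hi$ts[1], alp_hi$ts[1])  # both criteria first satisfied
    hit_rows(ts, sprintf("lab ALT=%g U/L & ALP=%g U/L (>= %gx ULN)",
                         alt_hi$value[1], alp_hi$value[1], p$uln_multiple))
  },
  L7 = function(slice, defn) {
    p <- defn$params
    out <- NULL
    cr <- lab_series(slice, "creatinine")
    if (nrow(cr) >= 2) {
      # baseline: the lower of the value at admission (within the lookback
      # window) and the in-stay minimum = the series minimum
      base <- min(cr$value)
      hi <- cr[cr$value > p$creatinine_fold * base, , drop = FALSE]
      if (nrow(hi) > 0) {
        out <- rbind(out, hit_rows(hi$ts, sprintf(
          "lab creatinine=%g umol/L > %gx baseline %g", hi$value,
          p$creatinine_fold, base)))
      }
    }
    eg <- lab_series(slice, "eGFR")
    if (nrow(eg) >= 2) {
      base <- eg$value[1]
      lo <- eg[-1, , drop = FALSE]
      lo <- lo[lo$value <= (1 - p$egfr_drop_fraction) * base, , drop = FALSE]
      if (nrow(lo) > 0) {
        out <- rbind(out, hit_rows(lo$ts, sprintf(
          "lab eGFR=%g mL/min, >= %g%% below baseline %g", lo$value,
          100 * p$egfr_drop_fraction, base)))
      }
    }
    # oliguria clause: evaluated only when a urine-output series is present
    uo <- lab_series(slice, "urine_output_rate")
    if (nrow(uo) >= 2) {
      low <- uo$value < p$urine_below
      r <- rle(low)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values & r$lengths >= 2)) {
        span <- hours_between(uo$ts[ends[k]], uo$ts[starts[k]])
        if (span > p$urine_min_hours) {
          out <- rbind(out, hit_rows(uo$ts[ends[k]], sprintf(
            "urine output < %g mL/(kg.h) sustained %.1f h", p$urine_below, span)))
        }
      }
    }
    out
  },
  L8 = function(slice, defn) {
    p <- defn$params
    lab_threshold_hits(slice, defn, c("PT", "APTT", "INR"), function(lb) {
      (lb$analyte == "PT" & lb$value > p$pt_above) |
        (lb$analyte == "APTT" & lb$value > p$aptt_above) |
        (lb$analyte == "INR" & lb$value > p$inr_above)
    })
  },
  L9 = function(slice, defn) {
    lab_threshold_hits(slice, defn, "platelets",
                       function(lb) lb$value < defn$params$platelets_below)
  },
  L10 = function(slice, defn) {
    if (excluded_by_context(slice, defn)) return(NULL)
    p <- defn$params
    lab_threshold_hits(slice, defn, "TSH", function(lb) {
      lb$value >= p$tsh_at_least | lb$value < p$tsh_below
    })
  },
  L11 = function(slice, defn) {
    lab_threshold_hits(slice, defn, "WBC",
                       function(lb) lb$value < defn$params$wbc_below)
  },
  L12 = function(slice, defn) {
    if (excluded_by_context(slice, defn)) return(NULL)
    p <- defn$params
    out <- lab_threshold_hits(slice, defn, "CK",
                              function(lb) lb$value > p$ck_fold * p$ck_uln)
    ev <- event_hits(slice, defn, p$event_codes)
    rbind(out, ev)
  },
  L13 = function(slice, defn) {
    if (!ctx_flag(slice, "chronic_renal_failure")) return(NULL)
    lab_threshold_hits(slice, defn, "hemoglobin",
                       function(lb) lb$value > defn$params$hemoglobin_above)
  },
  L14 = function(slice, defn) {
    event_hits(slice, defn, defn$params$event_codes)
  },
  L15 = function(slice, defn) {
    if (excluded_by_context(slice, defn)) return(NULL)
    lab_threshold_hits(slice, defn, "uric_acid",
                       function(lb) lb$value > defn$params$uric_acid_above)
  },
  L16 = function(slice, defn) {
    lab_threshold_hits(slice, defn, "systolic_bp",
                       function(lb) lb$value < defn$params$systolic_below)
  },
  L17 = function(slice, defn) {
    p <- defn$params
    cuts <- c(drug_level_theophylline = p$theophylline_above,
              drug_level_digoxin = p$digoxin_above,
              drug_level_vancomycin = p$vancomycin_above,
              drug_level_gentamicin = p$gentamicin_above,
              drug_level_carbamazepine = p$carbamazepine_above)
    lab_threshold_hits(slice, defn, names(cuts),
                       function(lb) lb$value > unname(cuts[lb$analyte]))
  },
  T4 = function(slice, defn) {
    p <- defn$params
    out <- treatment_hits(slice, defn, p$names)
    # combination clause: glucocorticoid together with epinephrine
    m <- slice$meds
    cort <- m[m$drug_class %in% p$combo_class, , drop = FALSE]
    epi <- m[m$drug_name %in% p$combo_name, , drop = FALSE]
    if (nrow(cort) > 0 && nrow(epi) > 0) {
      ts <- max(min(cort$start_ts), min(epi$start_ts))
      out <- rbind(out, hit_rows(ts, sprintf(
        "medication combination %s + %s", cort$drug_name[1], epi$drug_name[1])))
    }
    out
  },
  C5 = function(slice, defn) {
    if (excluded_by_context(slice, defn)) return(NULL)
    event_hits(slice, defn, defn$params$event_codes)
  },
  C7 = function(slice, defn) {
    p <- defn$params
    ev <- slice$events[slice$events$code %in% p$event_codes, , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    win <- slice$config$drug_window_days
    clause1 <- drug_context_ok(slice$meds, ev$ts, p$antithrombotic_classes,
                               NULL, win)
    clause2 <- ctx_flag(slice, "peptic_ulcer_history") &
      drug_context_ok(slice$meds, ev$ts, p$ulcerogenic_classes, NULL, win) &
      !drug_context_ok(slice$meds, ev$ts, "PPI", NULL, win)
    ev <- ev[clause1 | clause2, , drop = FALSE]
    hit_rows(ev$ts, event_evidence(ev))
  },
  C8 = function(slice, defn) {
    event_hits(slice, defn, defn$params$event_codes,
               exclude_event_flags = "pre_existing_cough")
  },
  I1 = function(slice, defn) {
    m <- slice$meds
    sel <- m$abrupt_stop
    if (isTRUE(slice$config$i1_include_dose_reduction)) sel <- sel | m$dose_reduced
    m <- m[sel, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    ts <- ifelse(is.na(m$stop_ts), m$start_ts, m$stop_ts)
    ts <- as.POSIXct(ts, origin = "1970-01-01", tz = "UTC")
    hit_rows(ts, sprintf("medication %s stopped abruptly", m$drug_name))
  }
)

# plain treatment and symptom triggers share the generic predicates
for (.id in c("T1", "T2", "T3", "T5", "T6", "T7", "T8", "T9", "T10")) {
  .trigger_predicates[[.id]] <- function(slice, defn) {
    treatment_hits(slice, defn, defn$params$names)
  }
}
for (.id in c("C1", "C2", "C3", "C4", "C6")) {
  .trigger_predicates[[.id]] <- function(slice, defn) {
    event_hits(slice, defn, defn$params$event_codes)
  }
}
rm(.id)

admission_slices <- function(cohort, config) {
  ids <- cohort$admissions$admission_id
  meds <- split(cohort$medications, factor(cohort$medications$admission_id, ids))
  labs <- split(cohort$labs, factor(cohort$labs$admission_id, ids))
  events <- split(cohort$events, factor(cohort$events$admission_id, ids))
  ctx <- cohort$context[match(ids, cohort$context$admission_id), ]
  lapply(seq_along(ids), function(i) {
    list(admission_id = ids[i],
         adm = cohort$admissions[i, ],
         meds = meds[[i]], labs = labs[[i]], events = events[[i]],
         ctx = as.list(ctx[i, ]),
         config = config)
  })
}

apply_counting_policy <- function(hits, config) {
  if (nrow(hits) == 0) return(hits)
  hits <- arrange(hits, .data$admission_id, .data$trigger_id, .data$ts)
  if (config$counting_policy == "per_stay") {
    hits <- hits %>%
      group_by(.data$admission_id, .data$trigger_id) %>%
      dplyr::slice(1) %>%
      ungroup()
  }
  arrange(hits, .data$admission_id, .data$trigger_id, .data$ts)
}

evaluate_slice <- function(slice, registry) {
  res <- lapply(registry, function(defn) {
    pred <- .trigger_predicates[[defn$id]]
    if (is.null(pred)) {
      abort(sprintf("no predicate implemented for trigger '%s'", defn$id))
    }
    h <- pred(slice, defn)
    if (is.null(h) || nrow(h) == 0) return(NULL)
    tibble(admission_id = slice$admission_id, trigger_id = defn$id,
           ts = h$ts, evidence = h$evidence)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(NULL)
  bind_rows(res)
}

#' Evaluate one trigger over a cohort
#'
#' @param defn a trigger definition (one entry of
#'   [default_trigger_registry()]).
#' @param cohort a `gtt_cohort`.
#' @param config a [gtt_config()].
#' @return tibble of hits (`admission_id`, `trigger_id`, `ts`, `evidence`),
#'   deduplicated per the counting policy.
#' @export
evaluate_trigger <- function(defn, cohort, config = gtt_config()) {
  evaluate_cohort(cohort, registry = setNames(list(defn), defn$id),
                  config = config)
}

#' Evaluate a trigger registry over a cohort
#'
#' Runs every registered screening rule over every admission. A hit requires
#' the rule's threshold/event condition, its drug-context requirement (a drug
#' of the named class active within the context window before the
#' observation) and none of its exclusion clauses. Deterministic given the
#' cohort and registry; output is ordered by (admission_id, trigger_id).
#'
#' @param cohort a `gtt_cohort`.
#' @param registry list of trigger definitions (default: the full 36-rule
#'   registry).
#' @param config a [gtt_config()].
#' @return hit table tibble with columns `admission_id`, `trigger_id`, `ts`,
#'   `evidence`.
#' @export
evaluate_cohort <- function(cohort, registry = default_trigger_registry(),
                            config = gtt_config()) {
  stopifnot(inherits(cohort, "gtt_cohort"))
  if (length(registry) == 0) abort("empty trigger registry")
  slices <- admission_slices(cohort, config)
  res <- lapply(slices, evaluate_slice, registry = registry)
  res <- res[!vapply(res, is.null, logical(1))]
  hits <- if (length(res)) bind_rows(res) else empty_hits()
  apply_counting_policy(hits, config)
}

#' Per-trigger activation summary
#'
#' @param hits hit table from [evaluate_cohort()].
#' @param registry the registry the hits were computed under.
#' @return list with `per_trigger` (tibble `trigger_id`, `module`,
#'   `positives`, zero-count triggers included), `n_triggers_fired` and
#'   `n_patients_with_hit`.
#' @export
trigger_activation_summary <- function(hits, registry = default_trigger_registry()) {
  ids <- vapply(registry, `[[`, character(1), "id")
  modules <- vapply(registry, `[[`, character(1), "module")
  counts <- table(factor(hits$trigger_id, levels = ids))
  per_trigger <- tibble(trigger_id = ids, module = unname(modules),
                        positives = as.integer(counts))
  list(per_trigger = per_trigger,
       n_triggers_fired = sum(per_trigger$positives > 0),
       n_patients_with_hit = length(unique(hits$admission_id)))
}
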