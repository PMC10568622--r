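# metrics module: PPV table, the three cohort rates, distribution tables,
# monthly surveillance series and the sample-size formula. All quantities
# are computed in full precision; rounding happens only at rendering
# (render_round(), half-to-even, 2 decimals).

#' Per-trigger positive and detection counts
#'
#' Counts, for each registered trigger, its positive firings and its
#' ADE-detection pairs (one pair per ADE-trigger link; an ADE identified by
#' more than one trigger is counted once per linking trigger).
#'
#' @param hits hit table from [evaluate_cohort()].
#' @param ades ADE tibble after [causality_filter()] (with
#'   `linked_triggers`).
#' @param registry trigger registry (default full list).
#' @return tibble `trigger_id`, `module`, `positives`, `detections`.
#' @export
trigger_counts <- function(hits, ades, registry = default_trigger_registry()) {
  ids <- vapply(registry, `[[`, character(1), "id")
  modules <- vapply(registry, `[[`, character(1), "module")
  pos <- table(factor(hits$trigger_id, levels = ids))
  link_ids <- unlist(split_semi(ades$linked_triggers))
  det <- table(factor(link_ids, levels = ids))
  tibble(trigger_id = ids, module = unname(modules),
         positives = as.integer(pos), detections = as.integer(det))
}

#' Positive-predictive-value table
#'
#' PPV per trigger = 100 x detections / positives, undefined (NA, rendered
#' em-dash) for triggers that never fired; plus an overall row computed from
#' the column sums.
#'
#' @param counts tibble with `trigger_id`, `positives`, `detections`
#'   (from [trigger_counts()] or the study-counts fixture).
#' @return tibble with a `ppv_percent` column and a final `Total` row.
#' @export
ppv_table <- function(counts) {
  stopifnot(all(c("trigger_id", "positives", "detections") %in% names(counts)))
  if (any(counts$detections > counts$positives)) {
    abort("detections exceed positives for at least one trigger")
  }
  per <- counts %>%
    mutate(ppv_percent = if_else(.data$positives > 0,
                                 100 * .data$detections / .data$positives,
                                 NA_real_))
  total <- tibble(trigger_id = "Total",
                  positives = sum(per$positives),
                  detections = sum(per$detections),
                  ppv_percent = if (sum(per$positives) > 0)
                    100 * sum(per$detections) / sum(per$positives) else NA_real_)
  if ("module" %in% names(per)) total$module <- ""
  out <- bind_rows(per, total)
  class(out) <- c("gtt_ppv_table", class(out))
  out
}

#' @export
print.gtt_ppv_table <- function(x, ...) {
  y <- as_tibble(x)
  y$ppv_percent <- ifelse(is.na(y$ppv_percent), "—",
                          sprintf("%.2f", render_round(y$ppv_percent)))
  print(y, n = nrow(y))
  invisible(x)
}

#' Overall PPV (percent) from a PPV table
#' @param ppv a [ppv_table()] result.
#' @return numeric scalar (full precision).
#' @export
overall_ppv <- function(ppv) {
  ppv$ppv_percent[ppv$trigger_id == "Total"]
}

#' Cohort ADE rate panel
#'
#' The three surveillance rates: occurrence rate (percent of admissions with
#' at least one ADE), ADEs per 100 admissions, and ADEs per 1,000
#' patient-days.
#'
#' @param n_admissions number of admissions reviewed.
#' @param n_patients_with_ade admissions with at least one ADE.
#' @param n_ades total ADEs.
#' @param patient_days total patient-days (sum of lengths of stay).
#' @return a `gtt_rate_panel` list with the counts and the full-precision
#'   rates `incidence_percent`, `ades_per_100_admissions`,
#'   `ades_per_1000_patient_days`.
#' @export
rate_panel <- function(n_admissions, n_patients_with_ade, n_ades,
                       patient_days) {
  if (n_admissions <= 0) abort("rate panel needs a positive number of admissions")
  stopifnot(n_patients_with_ade >= 0, n_ades >= 0, patient_days > 0)
  structure(list(
    n_admissions = n_admissions,
    n_patients_with_ade = n_patients_with_ade,
    n_ades = n_ades,
    patient_days = patient_days,
    incidence_percent = 100 * n_patients_with_ade / n_admissions,
    ades_per_100_admissions = 100 * n_ades / n_admissions,
    ades_per_1000_patient_days = 1000 * n_ades / patient_days
  ), class = "gtt_rate_panel")
}

#' @export
print.gtt_rate_panel <- function(x, ...) {
  cat(sprintf("ADE occurrence rate: %.2f%% (%d/%d)\n",
              render_round(x$incidence_percent), x$n_patients_with_ade,
              x$n_admissions))
  cat(sprintf("ADEs per 100 admissions: %.2f (%d ADEs)\n",
              render_round(x$ades_per_100_admissions), x$n_ades))
  cat(sprintf("ADEs per 1,000 patient-days: %.2f (%g patient-days)\n",
              render_round(x$ades_per_1000_patient_days), x$patient_days))
  invisible(x)
}

#' Rate panel from patient-level data
#'
#' Patient-days are the sum of length of stay over the cohort's admissions.
#'
#' @param cohort a `gtt_cohort` (after eligibility filtering).
#' @param ades ADE tibble after [causality_filter()].
#' @return a `gtt_rate_panel`.
#' @export
rate_panel_from_data <- function(cohort, ades) {
  rate_panel(n_admissions = nrow(cohort$admissions),
             n_patients_with_ade = length(unique(ades$admission_id)),
             n_ades = nrow(ades),
             patient_days = sum(cohort$admissions$length_of_stay))
}

#' Monthly ADE-rate series
#'
#' Per calendar month of admission: ADEs per 1,000 patient-days and per 100
#' admissions (the time-tracking indices). Months within the calendar span
#' with no admissions are reported with NA rates.
#'
#' @param cohort a `gtt_cohort`.
#' @param ades ADE tibble after [causality_filter()].
#' @return tibble `month`, `n_admissions`, `patient_days`, `n_ades`,
#'   `ades_per_100_admissions`, `ades_per_1000_patient_days`.
#' @export
monthly_rate_series <- function(cohort, ades) {
  a <- cohort$admissions
  month_of <- function(ts) format(ts, "%Y-%m", tz = "UTC")
  a_month <- month_of(a$admit_ts)
  ade_month <- a_month[match(ades$admission_id, a$admission_id)]
  span <- seq(as.Date(paste0(min(a_month), "-01")),
              as.Date(paste0(max(a_month), "-01")), by = "month")
  months <- format(span, "%Y-%m")
  adm <- tapply(a$length_of_stay, factor(a_month, months), sum)
  n_adm <- table(factor(a_month, months))
  n_ade <- table(factor(ade_month, months))
  tibble(month = months,
         n_admissions = as.integer(n_adm),
         patient_days = as.numeric(ifelse(is.na(adm), 0, adm)),
         n_ades = as.integer(n_ade)) %>%
    mutate(
      ades_per_100_admissions = if_else(.data$n_admissions > 0,
                                        100 * .data$n_ades / .data$n_admissions,
                                        NA_real_),
      ades_per_1000_patient_days = if_else(.data$patient_days > 0,
                                           1000 * .data$n_ades / .data$patient_days,
                                           NA_real_))
}

add_pct <- function(df, count_col = "n") {
  df$percent <- 100 * df[[count_col]] / sum(df[[count_col]])
  df
}

#' ADE distribution tables
#'
#' Onset-time, system-organ, severity-grade and per-patient multiplicity
#' tables with counts and percentages. The organ-system table counts
#' symptom-level entries: an ADE involving several organ systems
#' (semicolon-separated in `organ_system`) contributes one entry per system,
#' so its total may exceed the number of ADEs.
#'
#' @param ades ADE tibble after [causality_filter()].
#' @return list of tibbles `onset`, `organ`, `severity`, `multiplicity`,
#'   each with `n` and `percent` columns.
#' @export
distribution_tables <- function(ades) {
  voc <- gtt_vocab()
  onset <- tibble(onset_bin = voc$onset_bins,
                  n = as.integer(table(factor(ades$onset_bin, voc$onset_bins))))
  onset <- add_pct(onset[onset$n > 0 | onset$onset_bin != ">8 days", ])
  organs <- unlist(split_semi(ades$organ_system))
  organ <- tibble(organ_system = voc$organ_system,
                  n = as.integer(table(factor(organs, voc$organ_system))))
  organ <- add_pct(organ)
  severity <- tibble(ctcae_grade = 1:5,
                     n = as.integer(table(factor(ades$ctcae_grade, 1:5))))
  severity <- add_pct(severity)
  per_patient <- table(table(ades$admission_id))
  multiplicity <- tibble(n_ades_per_patient = as.integer(names(per_patient)),
                         n_patients = as.integer(per_patient))
  multiplicity$percent <- 100 * multiplicity$n_patients /
    sum(multiplicity$n_patients)
  list(onset = onset, organ = organ, severity = severity,
       multiplicity = multiplicity)
}

#' Distribution tables from summary counts
#'
#' Same shape as [distribution_tables()] but computed from a summary-level
#' counts fixture (see [study_counts_fixture()]) rather than patient rows.
#'
#' @param fixture a study-counts fixture list.
#' @return list of tibbles `onset`, `organ`, `severity`.
#' @export
distribution_tables_from_counts <- function(fixture) {
  list(onset = add_pct(fixture$onset_counts),
       organ = add_pct(fixture$organ_counts),
       severity = add_pct(fixture$severity_counts))
}

#' Sample size for estimating a proportion
#'
#' N = Z^2 P (1 - P) / delta^2, rounded to the nearest integer.
#'
#' @param P anticipated proportion, in (0, 1).
#' @param Z standard-normal quantile (default 1.96, the 95% level).
#' @param delta absolute sampling error, > 1e-6.
#' @return integer sample size.
#' @export
sample_size <- function(P, Z = 1.96, delta) {
  if (!is.finite(P) || P <= 0 || P >= 1) {
    abort("P must lie strictly between 0 and 1")
  }
  if (!is.finite(delta) || delta < 1e-6) {
    abort("delta must be positive (at least 1e-6)")
  }
  n <- Z^2 * P * (1 - P) / delta^2
  as.integer(floor(n + 0.5))
}
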