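# adjudication module: reviewer decisions as data, plus the scoring
# instruments — Naranjo causality, CTCAE severity, onset binning and
# ADE-to-trigger linkage. The two-tier human review itself is out of scope;
# the pipeline scores and validates reviewer input, it never infers
# causality.

#' The Naranjo item-weight table
#'
#' The ten questions of the adverse-drug-reaction probability scale with
#' their yes / no / unknown weights, shipped as a data file for
#' auditability.
#'
#' @return tibble with columns `item`, `question`, `yes`, `no`, `unknown`.
#' @export
naranjo_weights <- function() {
  path <- system.file("extdata", "naranjo_items.csv", package = "gttade")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Naranjo causality category from a score
#'
#' At least 9: definite; 5-8: probable; 1-4: possible; 0 or below: doubtful.
#'
#' @param score integer vector of Naranjo scores.
#' @return character vector of categories.
#' @export
naranjo_category <- function(score) {
  dplyr::case_when(score >= 9 ~ "definite",
                   score >= 5 ~ "probable",
                   score >= 1 ~ "possible",
                   TRUE ~ "doubtful")
}

#' Score a Naranjo questionnaire
#'
#' @param answers character vector of exactly 10 answers, each `"yes"`,
#'   `"no"` or `"unknown"`.
#' @param weights item-weight table (default [naranjo_weights()]).
#' @return list with `answers`, integer `score` and `category`.
#' @export
naranjo_score <- function(answers, weights = naranjo_weights()) {
  if (length(answers) != 10) {
    abort(sprintf("Naranjo questionnaire needs exactly 10 answers, got %d",
                  length(answers)))
  }
  answers <- tolower(answers)
  if (!all(answers %in% c("yes", "no", "unknown"))) {
    abort("Naranjo answers must be 'yes', 'no' or 'unknown'")
  }
  w <- as.matrix(weights[, c("yes", "no", "unknown")])
  score <- sum(w[cbind(seq_len(10), match(answers, colnames(w)))])
  list(answers = answers, score = as.integer(score),
       category = naranjo_category(score))
}

# vectorised scoring over q1..q10 columns of an adjudications frame
naranjo_score_frame <- function(df, weights = naranjo_weights()) {
  qcols <- paste0("q", 1:10)
  missing <- setdiff(qcols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("adjudications missing Naranjo answer column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  w <- as.matrix(weights[, c("yes", "no", "unknown")])
  score <- rep(0L, nrow(df))
  for (i in 1:10) {
    ans <- tolower(as.character(df[[qcols[i]]]))
    if (!all(ans %in% c("yes", "no", "unknown"))) {
      abort(sprintf("invalid Naranjo answer in column %s", qcols[i]))
    }
    score <- score + as.integer(w[i, match(ans, colnames(w))])
  }
  score
}

#' CTCAE grade from a severity descriptor
#'
#' Bijective mapping of the five severity descriptors onto grades 1-5:
#' mild symptoms with no intervention indicated (1); minimal, local or
#' noninvasive intervention indicated (2); severe or medically significant,
#' hospitalization indicated or prolonged (3); life-threatening consequences
#' (4); death (5).
#'
#' @param descriptor character vector of descriptors (see
#'   `gtt_vocab()$severity_descriptors`).
#' @return integer vector of grades in 1..5.
#' @export
ctcae_grade_from_descriptor <- function(descriptor) {
  map <- c(mild_no_intervention = 1L, minimal_local_noninvasive = 2L,
           severe_or_hospitalization = 3L, life_threatening = 4L,
           death = 5L)
  unknown <- setdiff(unique(descriptor), names(map))
  if (length(unknown) > 0) {
    abort(sprintf("unknown severity descriptor(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  unname(map[descriptor])
}

#' Bin ADE onset time relative to drug administration
#'
#' Onsets before admission are binned `prior_to_admission`; otherwise the
#' delay from first administration of the suspect drug is binned on
#' half-open intervals (lower, upper]: up to 5 h, 5 h-1 day, 1-2 days,
#' 2-4 days, 4-8 days, over 8 days.
#'
#' @param onset_ts,admin_ts,admit_ts POSIXct vectors (onset of the event,
#'   first administration of the suspect drug, hospital admission).
#' @return character vector of bins.
#' @export
onset_bin <- function(onset_ts, admin_ts, admit_ts) {
  bad <- !is.na(onset_ts) & !is.na(admin_ts) & !is.na(admit_ts) &
    onset_ts >= admit_ts & onset_ts < admin_ts
  if (any(bad)) {
    abort("onset after admission but before first administration of the suspect drug")
  }
  h <- hours_between(onset_ts, admin_ts)
  dplyr::case_when(
    onset_ts < admit_ts ~ "prior_to_admission",
    h <= 5 ~ "<=5 h",
    h <= 24 ~ "5 h-1 day",
    h <= 48 ~ "1-2 days",
    h <= 96 ~ "2-4 days",
    h <= 192 ~ "4-8 days",
    TRUE ~ ">8 days"
  )
}

#' Read reviewer adjudications
#'
#' Reads `adjudications.csv` (one row per candidate ADE: suspect drugs,
#' timestamps, organ system(s), severity descriptor, the 10 Naranjo answers
#' `q1`..`q10`, semicolon-separated linked trigger ids) and derives the
#' scored fields: Naranjo score and category, CTCAE grade, onset bin,
#' whether the event occurred during the stay.
#'
#' @param path CSV file path, or a data frame already in that shape.
#' @param cohort the `gtt_cohort` the adjudications refer to (needed for
#'   admission timestamps).
#' @return tibble of ADE records.
#' @export
read_adjudications <- function(path, cohort) {
  df <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  required <- c("ade_id", "admission_id", "suspect_drugs", "admin_ts",
                "onset_ts", "organ_system", "clinical_symptom",
                "severity_descriptor", paste0("q", 1:10), "linked_triggers",
                "medication_error")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("adjudications schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  a <- cohort$admissions
  idx <- match(df$admission_id, a$admission_id)
  if (anyNA(idx)) {
    abort(sprintf("referential error: adjudication admission_id(s) %s not in cohort",
                  paste(head(unique(df$admission_id[is.na(idx)]), 5), collapse = ", ")))
  }
  df$admin_ts <- parse_ts(df$admin_ts)
  df$onset_ts <- parse_ts(df$onset_ts)
  df$medication_error <- isTRUE_vec(df$medication_error)
  score <- naranjo_score_frame(df)
  admit <- a$admit_ts[idx]
  discharge <- a$discharge_ts[idx]
  df$naranjo_score <- score
  df$naranjo_category <- naranjo_category(score)
  df$ctcae_grade <- ctcae_grade_from_descriptor(df$severity_descriptor)
  df$onset_bin <- onset_bin(df$onset_ts, df$admin_ts, admit)
  df$occurred_during_stay <- df$onset_ts >= admit & df$onset_ts <= discharge
  df
}

#' Write adjudications to CSV
#' @param ades ADE tibble (e.g. the `adjudications` element of
#'   [generate_cohort()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjudications <- function(ades, path) {
  df <- ades
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_ts(df[[col]])
  }
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Keep causally-attributable ADEs
#'
#' Retains the ADEs adjudicated definite or probable on the Naranjo scale;
#' possible and doubtful candidates are dropped from all downstream
#' analyses. Idempotent.
#'
#' @param ades ADE tibble with a `naranjo_category` column.
#' @return the filtered tibble, with attribute `category_counts`.
#' @export
causality_filter <- function(ades) {
  counts <- ades %>% count(.data$naranjo_category, name = "n")
  out <- filter(ades, .data$naranjo_category %in% c("definite", "probable"))
  attr(out, "category_counts") <- counts
  out
}

#' Link adjudicated ADEs to trigger hits
#'
#' Partitions ADEs into trigger-detected (at least one linked hit) and
#' undetected, and counts detection pairs: an ADE identified by more than
#' one trigger contributes one pair per linking trigger.
#'
#' @param ades ADE tibble (after [causality_filter()]).
#' @param hits hit table from [evaluate_cohort()].
#' @return a `gtt_adjudicated` list: `ades` (with `n_links` and `detected`
#'   columns), `hits`, and `counts` (`n_ades`, `detected`, `undetected`,
#'   `detection_pairs`).
#' @export
link_ades_to_hits <- function(ades, hits) {
  links <- split_semi(ades$linked_triggers)
  hit_keys <- paste(hits$admission_id, hits$trigger_id)
  for (i in seq_along(links)) {
    if (length(links[[i]]) == 0) next
    keys <- paste(ades$admission_id[i], links[[i]])
    bad <- !keys %in% hit_keys
    if (any(bad)) {
      abort(sprintf(
        "referential error: ADE %s links trigger(s) %s with no hit on admission %s",
        ades$ade_id[i], paste(links[[i]][bad], collapse = ", "),
        ades$admission_id[i]))
    }
  }
  n_links <- lengths(links)
  out <- ades
  out$n_links <- n_links
  out$detected <- n_links > 0
  structure(list(ades = out, hits = hits,
                 counts = list(n_ades = nrow(out),
                               detected = sum(out$detected),
                               undetected = sum(!out$detected),
                               detection_pairs = sum(n_links))),
            class = "gtt_adjudicated")
}
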