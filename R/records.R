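# records module: cohort container, validation, CSV readers/writers,
# eligibility filtering.

.cohort_tables <- c("admissions", "medications", "labs", "events", "context")

.required_cols <- list(
  admissions  = c("admission_id", "age", "sex", "admit_ts", "discharge_ts",
                  "length_of_stay", "n_diagnoses", "allergy_history",
                  "allergy_list", "excluded_flags"),
  medications = c("admission_id", "drug_name", "drug_class", "start_ts",
                  "stop_ts", "abrupt_stop", "dose_reduced"),
  labs        = c("admission_id", "analyte", "value", "unit", "ts"),
  events      = c("admission_id", "code", "ts", "context_flags"),
  context     = c("admission_id", "diabetes", "thyroid_dysfunction",
                  "gout_or_hyperuricemia_history", "dementia_or_parkinson",
                  "chronic_renal_failure", "hepatobiliary_pancreatic_disease",
                  "primary_muscle_disease", "peptic_ulcer_history",
                  "on_parenteral_nutrition")
)

#' Construct a validated inpatient cohort
#'
#' Bundles the five tables of the tabular EHR data model (admissions,
#' medication administrations, laboratory results, clinical events, patient
#' context) into a `gtt_cohort`. Row-level validation failures are either
#' collected into a rejects report (`on_reject = "collect"`, the behaviour of
#' [load_cohort()]) or raised as an error (`"error"`). Referential failures
#' (a child row whose `admission_id` does not exist in `admissions`) are
#' always an error.
#'
#' @param admissions,medications,labs,events,context data frames matching the
#'   documented CSV schemas. Timestamp columns may be ISO-8601 strings or
#'   `POSIXct`.
#' @param on_reject `"collect"` or `"error"`.
#' @return a `gtt_cohort`: a named list of tibbles with attribute `rejects`
#'   (tibble of rejected rows with reasons).
#' @export
gtt_cohort <- function(admissions, medications = NULL, labs = NULL,
                       events = NULL, context = NULL,
                       on_reject = c("collect", "error")) {
  on_reject <- match.arg(on_reject)
  tabs <- list(
    admissions  = as_tibble(admissions),
    medications = if (is.null(medications)) empty_medications() else as_tibble(medications),
    labs        = if (is.null(labs)) empty_labs() else as_tibble(labs),
    events      = if (is.null(events)) empty_events() else as_tibble(events),
    context     = if (is.null(context)) empty_context(character()) else as_tibble(context)
  )
  for (nm in names(tabs)) check_schema(tabs[[nm]], nm)
  tabs <- coerce_cohort_types(tabs)
  check_referential(tabs)

  val <- validate_rows(tabs)
  if (on_reject == "error" && nrow(val$rejects) > 0) {
    abort(sprintf("cohort validation failed for %d row(s); first: %s",
                  nrow(val$rejects), val$rejects$reason[1]))
  }
  out <- val$tables
  # absent PatientContext rows are treated as all-false flags (exclusion
  # clauses need explicit positive evidence)
  missing_ctx <- setdiff(out$admissions$admission_id, out$context$admission_id)
  if (length(missing_ctx) > 0) {
    warn(sprintf("no patient context for %d admission(s); assuming all flags FALSE",
                 length(missing_ctx)))
    out$context <- bind_rows(out$context, empty_context(missing_ctx))
  }
  out$context <- out$context[out$context$admission_id %in% out$admissions$admission_id, ]
  structure(out, class = "gtt_cohort", rejects = val$rejects)
}

#' @export
print.gtt_cohort <- function(x, ...) {
  cat("<gtt_cohort>\n")
  for (nm in .cohort_tables) {
    cat(sprintf("  %-11s %6d rows\n", nm, nrow(x[[nm]])))
  }
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej) > 0) cat(sprintf("  rejects     %6d rows\n", nrow(rej)))
  invisible(x)
}

#' Rejected-row report of a cohort
#' @param cohort a `gtt_cohort`.
#' @return tibble with columns `table`, `admission_id`, `row`, `reason`.
#' @export
cohort_rejects <- function(cohort) {
  attr(cohort, "rejects") %||% empty_rejects()
}

check_schema <- function(df, table) {
  missing <- setdiff(.required_cols[[table]], names(df))
  if (length(missing) > 0) {
    abort(sprintf("schema error in '%s': missing column(s) %s",
                  table, paste(missing, collapse = ", ")))
  }
}

check_referential <- function(tabs) {
  ids <- tabs$admissions$admission_id
  for (nm in setdiff(.cohort_tables, "admissions")) {
    orphan <- which(!tabs[[nm]]$admission_id %in% ids)
    if (length(orphan) > 0) {
      abort(sprintf(
        "referential error in '%s': admission_id(s) %s (row %s) not present in admissions",
        nm,
        paste(head(unique(tabs[[nm]]$admission_id[orphan]), 5), collapse = ", "),
        paste(head(orphan, 5), collapse = ", ")))
    }
  }
}

coerce_cohort_types <- function(tabs) {
  a <- tabs$admissions
  a$admission_id <- as.character(a$admission_id)
  a$age <- as.integer(a$age)
  a$sex <- as.character(a$sex)
  a$admit_ts <- parse_ts(a$admit_ts)
  a$discharge_ts <- parse_ts(a$discharge_ts)
  a$length_of_stay <- as.numeric(a$length_of_stay)
  a$n_diagnoses <- as.integer(a$n_diagnoses)
  a$allergy_history <- as.logical(a$allergy_history)
  a$allergy_list <- ifelse(is.na(as.character(a$allergy_list)), "",
                           as.character(a$allergy_list))
  a$excluded_flags <- ifelse(is.na(as.character(a$excluded_flags)), "",
                             as.character(a$excluded_flags))
  tabs$admissions <- a

  m <- tabs$medications
  m$admission_id <- as.character(m$admission_id)
  m$drug_name <- tolower(as.character(m$drug_name))
  m$drug_class <- as.character(m$drug_class)
  m$start_ts <- parse_ts(m$start_ts)
  m$stop_ts <- parse_ts(m$stop_ts)
  m$abrupt_stop <- isTRUE_vec(m$abrupt_stop)
  m$dose_reduced <- isTRUE_vec(m$dose_reduced)
  tabs$medications <- m

  l <- tabs$labs
  l$admission_id <- as.character(l$admission_id)
  l$analyte <- as.character(l$analyte)
  l$value <- as.numeric(l$value)
  l$unit <- as.character(l$unit)
  l$ts <- parse_ts(l$ts)
  tabs$labs <- l

  e <- tabs$events
  e$admission_id <- as.character(e$admission_id)
  e$code <- as.character(e$code)
  e$ts <- parse_ts(e$ts)
  e$context_flags <- ifelse(is.na(as.character(e$context_flags)), "",
                            as.character(e$context_flags))
  tabs$events <- e

  ctx <- tabs$context
  ctx$admission_id <- as.character(ctx$admission_id)
  for (fl in setdiff(.required_cols$context, "admission_id")) {
    ctx[[fl]] <- isTRUE_vec(ctx[[fl]])
  }
  tabs$context <- ctx
  tabs
}

isTRUE_vec <- function(x) {
  out <- as.logical(x)
  out[is.na(out)] <- FALSE
  out
}

validate_rows <- function(tabs) {
  rejects <- list()
  voc <- gtt_vocab()

  a <- tabs$admissions
  reasons <- rep(NA_character_, nrow(a))
  flag <- function(cond, why) {
    ifelse(is.na(reasons) & cond, why, reasons)
  }
  reasons <- flag(is.na(a$age) | a$age < 0, "invalid age")
  reasons <- flag(!a$sex %in% voc$sex, "sex not in {male, female}")
  reasons <- flag(is.na(a$admit_ts) | is.na(a$discharge_ts), "missing stay timestamps")
  reasons <- flag(!is.na(a$admit_ts) & !is.na(a$discharge_ts) &
                    a$discharge_ts < a$admit_ts, "discharge before admission")
  reasons <- flag(is.na(a$length_of_stay) | a$length_of_stay < 1,
                  "eligibility: length of stay below 1 day")
  bad_flags <- vapply(split_semi(a$excluded_flags),
                      function(v) any(!v %in% voc$excluded_flags), logical(1))
  reasons <- flag(bad_flags, "unknown excluded_flags value")
  bad_a <- !is.na(reasons)
  if (any(bad_a)) {
    rejects$admissions <- tibble(table = "admissions",
                                 admission_id = a$admission_id[bad_a],
                                 row = which(bad_a), reason = reasons[bad_a])
  }
  keep_ids <- a$admission_id[!bad_a]
  tabs$admissions <- a[!bad_a, ]

  # child rows: vocabulary/invariant checks, then drop children of rejected
  # admissions into the rejects report (conservation: input = kept + rejected)
  child_check <- list(
    medications = function(m) {
      r <- rep(NA_character_, nrow(m))
      r <- ifelse(is.na(r) & !m$drug_class %in% voc$drug_class,
                  "drug_class not in vocabulary", r)
      r <- ifelse(is.na(r) & is.na(m$start_ts), "missing start_ts", r)
      r <- ifelse(is.na(r) & !is.na(m$stop_ts) & m$stop_ts < m$start_ts,
                  "stop before start", r)
      r
    },
    labs = function(l) {
      r <- rep(NA_character_, nrow(l))
      r <- ifelse(is.na(r) & !l$analyte %in% voc$analyte,
                  "analyte not in vocabulary", r)
      r <- ifelse(is.na(r) & (is.na(l$value) | !is.finite(l$value)),
                  "non-finite lab value", r)
      r <- ifelse(is.na(r) & l$unit != unname(voc$units[l$analyte]),
                  "unit does not match analyte's fixed unit", r)
      r <- ifelse(is.na(r) & is.na(l$ts), "missing timestamp", r)
      r
    },
    events = function(e) {
      r <- rep(NA_character_, nrow(e))
      r <- ifelse(is.na(r) & !e$code %in% voc$event_code,
                  "event code not in vocabulary", r)
      r <- ifelse(is.na(r) & is.na(e$ts), "missing timestamp", r)
      r
    },
    context = function(ctx) rep(NA_character_, nrow(ctx))
  )
  for (nm in names(child_check)) {
    df <- tabs[[nm]]
    r <- child_check[[nm]](df)
    r <- ifelse(is.na(r) & !df$admission_id %in% keep_ids,
                "parent admission rejected", r)
    bad <- !is.na(r)
    if (any(bad)) {
      rejects[[nm]] <- tibble(table = nm, admission_id = df$admission_id[bad],
                              row = which(bad), reason = r[bad])
    }
    tabs[[nm]] <- df[!bad, ]
  }
  list(tables = tabs,
       rejects = if (length(rejects)) bind_rows(rejects) else empty_rejects())
}

empty_rejects <- function() {
  tibble(table = character(), admission_id = character(),
         row = integer(), reason = character())
}
empty_medications <- function() {
  tibble(admission_id = character(), drug_name = character(),
         drug_class = character(), start_ts = parse_ts(character()),
         stop_ts = parse_ts(character()), abrupt_stop = logical(),
         dose_reduced = logical())
}
empty_labs <- function() {
  tibble(admission_id = character(), analyte = character(), value = numeric(),
         unit = character(), ts = parse_ts(character()))
}
empty_events <- function() {
  tibble(admission_id = character(), code = character(),
         ts = parse_ts(character()), context_flags = character())
}
empty_context <- function(ids) {
  out <- tibble(admission_id = as.character(ids))
  for (fl in setdiff(.required_cols$context, "admission_id")) {
    out[[fl]] <- rep(FALSE, length(ids))
  }
  out
}

#' Load a cohort from CSV files
#'
#' Reads the five cohort CSVs (`admissions.csv`, `medications.csv`,
#' `labs.csv`, `events.csv`, `context.csv`) from a directory, validates them
#' and returns a [gtt_cohort()]. Rows failing row-level validation are
#' collected into the rejects report (see [cohort_rejects()]), never silently
#' dropped; schema and referential problems are errors.
#'
#' @param dir directory containing the CSV files.
#' @param paths optional named list/vector overriding individual file paths
#'   (names among `admissions`, `medications`, `labs`, `events`, `context`).
#' @return a `gtt_cohort`.
#' @export
load_cohort <- function(dir = NULL, paths = NULL) {
  files <- setNames(file.path(dir %||% ".", paste0(.cohort_tables, ".csv")),
                    .cohort_tables)
  if (!is.null(paths)) files[names(paths)] <- unlist(paths)
  need <- files["admissions"]
  if (!file.exists(need)) abort(sprintf("admissions file not found: %s", need))
  read1 <- function(path) {
    if (!file.exists(path)) return(NULL)
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  gtt_cohort(admissions  = read1(files["admissions"]),
             medications = read1(files["medications"]),
             labs        = read1(files["labs"]),
             events      = read1(files["events"]),
             context     = read1(files["context"]))
}

#' Write a cohort to CSV files
#'
#' Inverse of [load_cohort()]: writes the five cohort tables as UTF-8 CSVs
#' with ISO-8601 minute timestamps. `write_cohort()` then `load_cohort()`
#' round-trips a valid cohort field-for-field.
#'
#' @param cohort a `gtt_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gtt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in .cohort_tables) {
    df <- cohort[[nm]]
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_ts(df[[col]])
    }
    readr::write_csv(df, file.path(dir, paste0(nm, ".csv")), na = "")
  }
  invisible(dir)
}

#' Apply the study eligibility criteria
#'
#' Retains admissions aged at least 65 years with a length of stay exceeding
#' one day and none of the exclusion flags (malignant tumour, organ
#' transplant, palliative care, ICU transfer). Child tables are filtered to
#' the retained admissions. Idempotent.
#'
#' @param cohort a `gtt_cohort`.
#' @return the filtered `gtt_cohort`, with attribute `exclusions`: a tibble
#'   of per-reason exclusion counts (an admission may count under several
#'   reasons).
#' @export
apply_eligibility <- function(cohort) {
  stopifnot(inherits(cohort, "gtt_cohort"))
  a <- cohort$admissions
  flags <- split_semi(a$excluded_flags)
  reason_tbl <- list(
    age_below_65 = a$age < 65,
    length_of_stay_not_exceeding_1_day = a$length_of_stay <= 1
  )
  for (fl in gtt_vocab()$excluded_flags) {
    reason_tbl[[fl]] <- vapply(flags, function(v) fl %in% v, logical(1))
  }
  excl_mat <- do.call(cbind, reason_tbl)
  excluded <- rowSums(excl_mat) > 0
  report <- tibble(reason = colnames(excl_mat),
                   n = as.integer(colSums(excl_mat)))
  keep <- a$admission_id[!excluded]
  out <- cohort
  out$admissions <- a[!excluded, ]
  for (nm in setdiff(.cohort_tables, "admissions")) {
    out[[nm]] <- out[[nm]][out[[nm]]$admission_id %in% keep, ]
  }
  attr(out, "exclusions") <- report
  attr(out, "rejects") <- attr(cohort, "rejects")
  out
}

#' Exclusion report from an eligibility-filtered cohort
#' @param cohort output of [apply_eligibility()].
#' @return tibble of exclusion counts per reason.
#' @export
eligibility_report <- function(cohort) {
  attr(cohort, "exclusions") %||%
    tibble(reason = character(), n = integer())
}
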