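# Orchestration: screen -> adjudicate -> report -> risk in one call, with a
# manifest recording the configuration the results were produced under.

#' Run the full screening pipeline
#'
#' Applies eligibility, evaluates the trigger registry, scores and filters
#' the reviewer adjudications, links ADEs to hits, and computes the PPV
#' table, rate panel, distribution tables, monthly series and risk models.
#' Deterministic given cohort, adjudications and configuration.
#'
#' @param cohort a `gtt_cohort` or a directory path for [load_cohort()].
#' @param adjudications adjudications CSV path or data frame (see
#'   [read_adjudications()]).
#' @param registry trigger registry (default [default_trigger_registry()]).
#' @param config a [gtt_config()].
#' @param out_dir optional output directory; when given, writes `hits.csv`,
#'   `ades.csv`, `ppv.csv`, `rates.json`, `risk.json`,
#'   `tables/<name>.csv` and `manifest.json`.
#' @param fit_risk fit the logistic risk model (needs at least 10 ADE
#'   admissions; default `TRUE`, silently skipped with a diagnostic entry
#'   when infeasible).
#' @return list with `cohort`, `hits`, `activation`, `ades`, `linked`,
#'   `ppv`, `rates`, `tables`, `monthly`, `comparison`, `risk`, `manifest`.
#' @export
run_pipeline <- function(cohort, adjudications,
                         registry = default_trigger_registry(),
                         config = gtt_config(), out_dir = NULL,
                         fit_risk = TRUE) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  cohort <- apply_eligibility(cohort)

  hits <- evaluate_cohort(cohort, registry, config)
  activation <- trigger_activation_summary(hits, registry)

  ades_all <- read_adjudications(adjudications, cohort)
  ades <- causality_filter(ades_all)
  linked <- link_ades_to_hits(ades, hits)

  counts <- trigger_counts(hits, linked$ades, registry)
  ppv <- ppv_table(counts)
  rates <- rate_panel_from_data(cohort, linked$ades)
  tables <- distribution_tables(linked$ades)
  monthly <- monthly_rate_series(cohort, linked$ades)

  cov <- assemble_covariates(cohort, linked$ades)
  comparison <- tryCatch(compare_groups(cov), error = function(e) e$message)
  risk <- if (fit_risk) {
    tryCatch(fit_logistic(cov), error = function(e) e$message)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gttade")),
    n_admissions = nrow(cohort$admissions),
    n_hits = nrow(hits),
    n_ades = linked$counts$n_ades,
    config = unclass(config),
    config_hash = rlang::hash(list(unclass(config),
                                   lapply(registry, unclass))))

  out <- list(cohort = cohort, hits = hits, activation = activation,
              ades = ades_all, linked = linked, ppv = ppv, rates = rates,
              tables = tables, monthly = monthly, comparison = comparison,
              risk = risk, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  hits <- res$hits
  hits$ts <- format_ts(hits$ts)
  readr::write_csv(hits, file.path(out_dir, "hits.csv"), na = "")
  write_adjudications(res$linked$ades, file.path(out_dir, "ades.csv"))
  readr::write_csv(as_tibble(res$ppv), file.path(out_dir, "ppv.csv"), na = "")
  r <- res$rates
  jsonlite::write_json(
    list(n_admissions = r$n_admissions,
         n_patients_with_ade = r$n_patients_with_ade,
         n_ades = r$n_ades, patient_days = r$patient_days,
         incidence_percent = render_round(r$incidence_percent),
         ades_per_100_admissions = render_round(r$ades_per_100_admissions),
         ades_per_1000_patient_days = render_round(r$ades_per_1000_patient_days)),
    file.path(out_dir, "rates.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(res$tables)) {
    readr::write_csv(res$tables[[nm]],
                     file.path(out_dir, "tables", paste0(nm, ".csv")), na = "")
  }
  readr::write_csv(res$monthly, file.path(out_dir, "tables", "monthly.csv"),
                   na = "")
  if (inherits(res$risk, "gtt_logit")) {
    jsonlite::write_json(
      list(coefficients = res$risk$coefficients,
           converged = res$risk$converged, n = res$risk$n,
           n_events = res$risk$n_events),
      file.path(out_dir, "risk.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
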