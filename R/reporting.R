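# Report assembly and the duplicate-submission registry. The clock is always
# injected (never read ambiently) so reports are reproducible; the registry
# is an append-only JSON-lines file keyed by patient + study so legitimate
# repeat TDM studies do not trigger the duplicate warning (a strict
# patient-only mode is available in the configuration).

#' Assemble a time-stamped TDM report
#'
#' Bundles the analysis of one profile into a single report object carrying
#' exactly one of a compartmental fit or an NCA result (per the chosen
#' route), the tachometer score, the dose recommendation, free-text
#' comments, the package version and a deterministic digest of the
#' configuration in force.
#'
#' @param profile The analyzed [tdm_profile()].
#' @param choice The `model_choice` from [select_model()] (or after
#'   [override_route()]).
#' @param rec The [recommend_dose()] result.
#' @param nca The `nca_result`, required when `choice$route` is
#'   `"nca_fallback"`.
#' @param comments Free-text clinician comments.
#' @param created_at Injected timestamp string (e.g. `format(Sys.time())`);
#'   required explicitly so report generation is deterministic under test.
#' @param config The `analysis_config` used for the analysis.
#' @return Object of class `tdm_report`.
#' @export
build_report <- function(profile, choice, rec, nca = NULL, comments = "",
                         created_at, config = default_config()) {
  stopifnot(inherits(profile, "tdm_profile"), inherits(choice, "model_choice"),
            inherits(rec, "dose_recommendation"))
  if (missing(created_at))
    stop("created_at must be supplied (injected clock)", call. = FALSE)
  compartmental <- choice$route %in% c("compartmental_1", "compartmental_2")
  if (compartmental && is.null(choice$fit))
    stop("compartmental route without a fit result", call. = FALSE)
  if (!compartmental && is.null(nca))
    stop("nca_fallback route requires an nca_result", call. = FALSE)
  fit <- choice$fit
  structure(list(
    patient_id = profile$patient_id,
    study = list(dose_number = profile$dose$dose_number,
                 time_origin = as.character(profile$dose$time_origin)),
    created_at = as.character(created_at),
    route = choice$route,
    reason_codes = choice$reason_codes,
    samples = active_samples(profile),
    n_excluded = sum(profile$samples$excluded),
    fit = if (compartmental) list(
      model_order = fit$model_order,
      params = unclass(fit$params),
      macro = fit$macro,
      macro_cv = as.list(fit$macro_cv),
      weighted_SS = fit$weighted_SS,
      predictions = fit$predictions,
      converged = fit$converged) else NULL,
    nca = if (!compartmental) list(
      lambda_z = nca$lambda_z,
      lambda_z_r2_adj = nca$lambda_z_r2_adj,
      n_terminal = nca$n_terminal,
      auc_last = nca$auc_last,
      auc_inf = nca$auc_inf,
      extrap_fraction = nca$extrap_fraction,
      clearance_CL = nca$clearance_CL,
      flags = as.list(nca$flags)) else NULL,
    gof = if (!is.null(choice$gof)) list(
      score = choice$gof$score,
      band = choice$gof$band,
      component_scores = choice$gof$component_scores) else NULL,
    recommendation = list(
      current_dose = rec$current_dose,
      recommended_dose = rec$recommended_dose,
      change_at_dose_number = rec$change_at_dose_number,
      total_doses = rec$total_doses,
      clearance_CL = rec$clearance_CL,
      target = list(kind = rec$target$kind, value = rec$target$value,
                    units_in = rec$target$units_in,
                    value_in = rec$target$value_in),
      predicted = unclass(rec$predicted),
      rounded_variants = lapply(rec$rounded_variants, function(v)
        list(dose = v$dose, exposure = unclass(v$exposure)))),
    comments = as.character(comments),
    software_version = as.character(utils::packageVersion("bustdm")),
    config_digest = config_digest(config)
  ), class = "tdm_report")
}

#' Serialize a report to JSON / read it back
#'
#' The JSON rendering is lossless: `report_from_json(report_to_json(x))`
#' reproduces every field.
#'
#' @param report A `tdm_report`.
#' @param path Optional path; when given the JSON is written there.
#' @return `report_to_json`: the JSON string (invisibly when written to
#'   `path`); `report_from_json`: the `tdm_report`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "tdm_report"))
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(17),
                          null = "null", dataframe = "columns")
  if (!is.null(path)) {
    writeLines(as.character(txt), path)
    return(invisible(txt))
  }
  txt
}

#' @rdname report_to_json
#' @param json A JSON string or path produced by `report_to_json`.
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  obj$samples <- as.data.frame(obj$samples)
  if (!is.null(obj$nca)) obj$nca$flags <- as.list(obj$nca$flags)
  if (!is.null(obj$fit)) obj$fit$macro_cv <- as.list(obj$fit$macro_cv)
  if (!is.null(obj$recommendation$rounded_variants))
    obj$recommendation$rounded_variants <-
      lapply(seq_len(nrow(obj$recommendation$rounded_variants)), function(i) {
        row <- obj$recommendation$rounded_variants[i, ]
        list(dose = row$dose, exposure = as.list(row$exposure))
      })
  structure(obj, class = "tdm_report")
}

#' Human-readable text rendering of a report
#'
#' Mirrors the four-screen clinical flow: data table, model and fit quality,
#' simulation, recommendation.
#'
#' @param x A `tdm_report`.
#' @param ... Unused.
#' @return Character vector of report lines, invisibly (also printed).
#' @export
format.tdm_report <- function(x, ...) {
  lines <- c(
    sprintf("BUSULFAN TDM REPORT  (%s)", x$created_at),
    sprintf("Patient %s | study dose %d | software %s | config %s",
            x$patient_id, x$study$dose_number, x$software_version,
            substr(x$config_digest, 1, 8)),
    "",
    "-- Patient data --",
    sprintf("  t=%6.1f min  C=%8.4f mg/L", x$samples$time, x$samples$conc),
    sprintf("  (%d excluded point(s) not shown)", x$n_excluded),
    "",
    "-- Model fit --",
    sprintf("  route: %s [%s]", x$route,
            paste(x$reason_codes, collapse = ", ")))
  if (!is.null(x$fit))
    lines <- c(lines, sprintf("  %d-compartment fit, weighted SS %.4g, converged %s",
                              x$fit$model_order, x$fit$weighted_SS,
                              x$fit$converged))
  if (!is.null(x$nca))
    lines <- c(lines, sprintf("  NCA: lambda_z %.5g /min, AUCinf %.4g mg*min/L (%.0f%% extrapolated)",
                              x$nca$lambda_z, x$nca$auc_inf,
                              100 * x$nca$extrap_fraction))
  if (!is.null(x$gof))
    lines <- c(lines, sprintf("  goodness of fit: %.1f / 10 (%s)",
                              x$gof$score, x$gof$band))
  r <- x$recommendation
  lines <- c(lines, "",
             "-- Simulation & recommendation --",
             sprintf("  clearance %.4g L/min", r$clearance_CL),
             sprintf("  target: %s = %g %s", r$target$kind, r$target$value_in,
                     r$target$units_in),
             sprintf("  recommended dose %.1f mg (current %.1f mg), change at dose %d of %d",
                     r$recommended_dose, r$current_dose,
                     r$change_at_dose_number, r$total_doses),
             sprintf("  predicted AUC/dose %.1f mg*min/L, Cavg,ss %.3f mg/L",
                     r$predicted$auc_per_dose, r$predicted$cavg_ss))
  if (nzchar(x$comments))
    lines <- c(lines, "", "-- Comments --", paste(" ", x$comments))
  lines
}

#' @export
print.tdm_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Open (or create) a report registry
#'
#' The registry is an append-only JSON-lines file: one line per registered
#' report, never rewritten, so it doubles as an audit log.
#'
#' @param path Path to the registry file.
#' @return Object of class `report_registry`.
#' @export
report_registry <- function(path) {
  structure(list(path = path), class = "report_registry")
}

.registry_entries <- function(registry) {
  if (!file.exists(registry$path)) return(list())
  lines <- readLines(registry$path, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = TRUE)
}

.study_key <- function(patient_id, study, mode) {
  if (mode == "patient_only") patient_id
  else paste(patient_id, study$dose_number, study$time_origin, sep = "|")
}

#' Register a report, warning on duplicates
#'
#' Appends the report to the registry. When a report for the same patient
#' and study (or same patient, in `registry_key = "patient_only"` mode) was
#' already registered, `duplicate_warning` is `TRUE` — storage still
#' proceeds; the warning informs, it does not block.
#'
#' @param registry A [report_registry()].
#' @param report A `tdm_report`.
#' @param config An `analysis_config` (`registry_key` mode).
#' @return List: `stored` (logical), `duplicate_warning` (logical),
#'   `report_id` (sequence number in the registry).
#' @export
register_report <- function(registry, report, config = default_config()) {
  stopifnot(inherits(registry, "report_registry"),
            inherits(report, "tdm_report"))
  entries <- .registry_entries(registry)
  key <- .study_key(report$patient_id, report$study, config$registry_key)
  prior_keys <- vapply(entries, function(e)
    .study_key(e$patient_id, e$study, config$registry_key), character(1))
  dup <- key %in% prior_keys
  entry <- list(report_id = length(entries) + 1L,
                patient_id = report$patient_id,
                study = report$study,
                created_at = report$created_at,
                route = report$route,
                recommended_dose = report$recommendation$recommended_dose)
  line <- as.character(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = I(17)))
  con <- file(registry$path, open = "a")
  on.exit(close(con), add = TRUE)
  writeLines(line, con)
  list(stored = TRUE, duplicate_warning = dup,
       report_id = entry$report_id)
}

#' Number of reports in a registry
#' @param registry A [report_registry()].
#' @return Integer count.
#' @export
registry_count <- function(registry) {
  length(.registry_entries(registry))
}
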