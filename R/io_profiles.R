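# Profile data model and file I/O.
#
# Canonical internal units: concentrations mg/L, times minutes relative to
# infusion START of the studied dose, masses mg, weights kg. All unit
# conversion happens once, at parse time.

#' Construct an infusion dose event
#'
#' @param dose_amount Dose administered (mg), > 0.
#' @param infusion_duration Zero-order infusion duration \eqn{T_{inf}} (min).
#' @param dosing_interval_tau Dosing interval \eqn{\tau} (min), >
#'   `infusion_duration`.
#' @param dose_number Index of the studied dose within the course.
#' @param total_planned_doses Planned number of doses in the course.
#' @param time_origin Timestamp or 0-reference of infusion start; kept as an
#'   opaque label (sample times are always relative to it).
#' @return An object of class `infusion_event`.
#' @export
#' @examples
#' infusion_event(100, 120, 360, 5, 16)
infusion_event <- function(dose_amount, infusion_duration, dosing_interval_tau,
                           dose_number = 1L, total_planned_doses = 1L,
                           time_origin = 0) {
  stopifnot(is.numeric(dose_amount), length(dose_amount) == 1L)
  if (!(dose_amount > 0))
    stop("dose_amount must be > 0", call. = FALSE)
  if (!(infusion_duration > 0 && infusion_duration < dosing_interval_tau))
    stop("need 0 < infusion_duration < dosing_interval_tau", call. = FALSE)
  dose_number <- as.integer(dose_number)
  total_planned_doses <- as.integer(total_planned_doses)
  if (!(dose_number >= 1L && dose_number <= total_planned_doses))
    stop("need 1 <= dose_number <= total_planned_doses", call. = FALSE)
  structure(list(
    dose_amount = as.numeric(dose_amount),
    infusion_duration = as.numeric(infusion_duration),
    dosing_interval_tau = as.numeric(dosing_interval_tau),
    dose_number = dose_number,
    total_planned_doses = total_planned_doses,
    time_origin = time_origin
  ), class = "infusion_event")
}

#' Construct a TDM study profile
#'
#' @param patient_id Opaque patient identifier.
#' @param dosing_weight Dosing weight (kg).
#' @param dose An [infusion_event()].
#' @param samples `data.frame` with columns `time` (min since infusion
#'   start), `conc` (mg/L), and optionally `excluded` (logical) and `note`
#'   (character). Rows are sorted by time on construction; replicate times
#'   are allowed and both enter the fit.
#' @param assay_lloq Optional assay lower limit of quantification (mg/L).
#' @return An object of class `tdm_profile`.
#' @export
#' @examples
#' p <- tdm_profile("pt1", 30, infusion_event(100, 120, 360),
#'                  data.frame(time = c(135, 240, 360),
#'                             conc = c(4.2, 2.1, 0.9)))
#' n_active_samples(p)
tdm_profile <- function(patient_id, dosing_weight, dose, samples,
                        assay_lloq = NA_real_) {
  stopifnot(inherits(dose, "infusion_event"), is.data.frame(samples))
  if (!(is.numeric(dosing_weight) && dosing_weight > 0))
    stop("dosing_weight must be a positive number (kg)", call. = FALSE)
  req <- c("time", "conc")
  if (!all(req %in% names(samples)))
    stop("samples need columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (is.null(samples$excluded)) samples$excluded <- FALSE
  if (is.null(samples$note)) samples$note <- ""
  samples$excluded <- as.logical(samples$excluded)
  samples$excluded[is.na(samples$excluded)] <- FALSE
  samples$note <- as.character(samples$note)
  samples$note[is.na(samples$note)] <- ""
  if (any(!is.finite(samples$time)) || any(samples$time < 0))
    stop("sample times must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(samples$conc)) || any(samples$conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  ord <- order(samples$time)
  samples <- samples[ord, c("time", "conc", "excluded", "note"), drop = FALSE]
  rownames(samples) <- NULL
  if (!any(!samples$excluded))
    stop("profile needs at least one non-excluded sample", call. = FALSE)
  structure(list(
    patient_id = as.character(patient_id),
    dosing_weight = as.numeric(dosing_weight),
    dose = dose,
    samples = samples,
    assay_lloq = as.numeric(assay_lloq)
  ), class = "tdm_profile")
}

#' @export
print.tdm_profile <- function(x, ...) {
  cat(sprintf("<tdm_profile> patient %s, %.1f kg\n", x$patient_id,
              x$dosing_weight))
  cat(sprintf("  dose %g mg over %g min, tau %g min (dose %d of %d)\n",
              x$dose$dose_amount, x$dose$infusion_duration,
              x$dose$dosing_interval_tau, x$dose$dose_number,
              x$dose$total_planned_doses))
  cat(sprintf("  %d samples (%d excluded)\n", nrow(x$samples),
              sum(x$samples$excluded)))
  invisible(x)
}

# ---- unit handling ---------------------------------------------------------

#' Convert concentrations to mg/L
#'
#' Supported unit strings: `mg/L`, `ug/mL` (identical scale), `ng/mL`,
#' `mg/dL`, `umol/L`/`uM` (via the configured molar mass).
#' Conversion is idempotent by construction: mg/L maps to itself.
#'
#' @param x Numeric concentrations.
#' @param unit Unit string.
#' @param molar_mass_g_mol Molar mass for molar units (g/mol).
#' @return Concentrations in mg/L.
#' @export
conc_to_mgL <- function(x, unit, molar_mass_g_mol = 246.3) {
  u <- gsub("\\s", "", tolower(unit))
  u <- gsub("µ", "u", u)
  factor <- switch(u,
    "mg/l"   = 1,
    "ug/ml"  = 1,
    "mcg/ml" = 1,
    "ng/ml"  = 1e-3,
    "ug/l"   = 1e-3,
    "mg/dl"  = 10,
    "umol/l" = ,
    "um"     = molar_mass_g_mol / 1000,
    stop("unknown concentration unit: ", unit, call. = FALSE))
  x * factor
}

# ---- file I/O --------------------------------------------------------------

.profile_csv_columns <- c("patient_id", "dosing_weight_kg", "dose_mg",
                          "infusion_duration_min", "tau_min", "dose_number",
                          "total_doses", "sample_time_min", "conc",
                          "conc_unit", "excluded", "note")

#' Read a TDM profile from CSV or JSON
#'
#' CSV layout: one row per sample with the dose fields repeated
#' (`patient_id, dosing_weight_kg, dose_mg, infusion_duration_min, tau_min,
#' dose_number, total_doses, sample_time_min, conc, conc_unit, excluded,
#' note`). JSON: a single object mirroring the profile fields with a
#' `samples` array. Concentrations are normalized to mg/L at parse time.
#'
#' @param source Path to the file.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @param molar_mass_g_mol Molar mass used for micromolar units.
#' @return A [tdm_profile()].
#' @export
read_profile <- function(source, format = c("auto", "csv", "json"),
                         molar_mass_g_mol = 246.3) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(source)),
                     csv = "csv", json = "json",
                     stop("cannot infer format from extension; pass format=",
                          call. = FALSE))
  }
  if (format == "csv") {
    df <- utils::read.csv(source, stringsAsFactors = FALSE,
                          colClasses = c(note = "character"))
    missing_cols <- setdiff(setdiff(.profile_csv_columns, c("excluded", "note",
                                                            "conc_unit")),
                            names(df))
    if (length(missing_cols) > 0L)
      stop("missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (is.null(df$conc_unit)) df$conc_unit <- "mg/L"
    if (is.null(df$excluded)) df$excluded <- FALSE
    if (is.null(df$note)) df$note <- ""
    conc <- conc_to_mgL(df$conc, df$conc_unit[1L], molar_mass_g_mol)
    dose <- infusion_event(df$dose_mg[1L], df$infusion_duration_min[1L],
                           df$tau_min[1L], df$dose_number[1L],
                           df$total_doses[1L])
    tdm_profile(df$patient_id[1L], df$dosing_weight_kg[1L], dose,
                data.frame(time = df$sample_time_min, conc = conc,
                           excluded = df$excluded, note = df$note,
                           stringsAsFactors = FALSE))
  } else {
    obj <- jsonlite::fromJSON(source, simplifyVector = TRUE)
    need <- c("patient_id", "dosing_weight_kg", "dose", "samples")
    missing_keys <- setdiff(need, names(obj))
    if (length(missing_keys) > 0L)
      stop("missing required key(s): ", paste(missing_keys, collapse = ", "),
           call. = FALSE)
    s <- as.data.frame(obj$samples)
    unit <- if (is.null(obj$conc_unit)) "mg/L" else obj$conc_unit
    dose <- infusion_event(obj$dose$dose_mg, obj$dose$infusion_duration_min,
                           obj$dose$tau_min,
                           if (is.null(obj$dose$dose_number)) 1L else obj$dose$dose_number,
                           if (is.null(obj$dose$total_doses)) 1L else obj$dose$total_doses)
    tdm_profile(obj$patient_id, obj$dosing_weight_kg, dose,
                data.frame(time = s$time_min,
                           conc = conc_to_mgL(s$conc, unit, molar_mass_g_mol),
                           excluded = if (is.null(s$excluded)) FALSE else s$excluded,
                           note = if (is.null(s$note)) "" else s$note,
                           stringsAsFactors = FALSE),
                assay_lloq = if (is.null(obj$assay_lloq)) NA_real_ else obj$assay_lloq)
  }
}

#' Write a TDM profile to CSV or JSON
#'
#' Inverse of [read_profile()]: a write-then-read round trip reproduces all
#' fields and exclusion flags. Output is always in canonical units (mg/L).
#'
#' @param profile A [tdm_profile()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(profile, "tdm_profile"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), csv = "csv",
                     json = "json", stop("cannot infer format", call. = FALSE))
  s <- profile$samples
  if (format == "csv") {
    df <- data.frame(patient_id = profile$patient_id,
                     dosing_weight_kg = profile$dosing_weight,
                     dose_mg = profile$dose$dose_amount,
                     infusion_duration_min = profile$dose$infusion_duration,
                     tau_min = profile$dose$dosing_interval_tau,
                     dose_number = profile$dose$dose_number,
                     total_doses = profile$dose$total_planned_doses,
                     sample_time_min = s$time, conc = s$conc,
                     conc_unit = "mg/L", excluded = s$excluded,
                     note = s$note, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    obj <- list(patient_id = profile$patient_id,
                dosing_weight_kg = profile$dosing_weight,
                dose = list(dose_mg = profile$dose$dose_amount,
                            infusion_duration_min = profile$dose$infusion_duration,
                            tau_min = profile$dose$dosing_interval_tau,
                            dose_number = profile$dose$dose_number,
                            total_doses = profile$dose$total_planned_doses),
                conc_unit = "mg/L",
                samples = data.frame(time_min = s$time, conc = s$conc,
                                     excluded = s$excluded, note = s$note,
                                     stringsAsFactors = FALSE))
    if (is.finite(profile$assay_lloq)) obj$assay_lloq <- profile$assay_lloq
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns")
  }
  invisible(path)
}

# ---- validation and exclusion ----------------------------------------------

validation_issue <- function(severity, code, message, sample_index = NA_integer_) {
  data.frame(severity = severity, code = code, message = message,
             sample_index = as.integer(sample_index),
             stringsAsFactors = FALSE)
}

#' Validate a profile against analysis preconditions
#'
#' Issues are returned, never raised: `error` issues block any fit or NCA,
#' `warning` issues inform the clinician (and feed the automatic
#' model-independent fallback logic downstream).
#'
#' Checks: at least `min_post_infusion_points` (default 3) non-excluded
#' post-infusion samples; post-infusion concentration rises exceeding
#' `monotone_rise_frac` (default 20\%) between consecutive non-excluded
#' samples raise a `non_monotone_decline` warning; non-excluded
#' concentrations below the assay LLOQ raise `below_lloq` warnings.
#'
#' @param profile A [tdm_profile()].
#' @param config An `analysis_config`.
#' @return A `data.frame` with columns `severity`, `code`, `message`,
#'   `sample_index`; zero rows when the profile is clean.
#' @export
validate_profile <- function(profile, config = default_config()) {
  stopifnot(inherits(profile, "tdm_profile"))
  issues <- list()
  s <- profile$samples
  act <- which(!s$excluded)
  tinf <- profile$dose$infusion_duration
  post <- act[s$time[act] >= tinf]
  if (length(post) < config$min_post_infusion_points) {
    issues[[length(issues) + 1L]] <- validation_issue(
      "error", "insufficient_post_infusion_points",
      sprintf("need >= %d non-excluded post-infusion samples, have %d",
              config$min_post_infusion_points, length(post)))
  }
  if (length(post) >= 2L) {
    tt <- s$time[post]; cc <- s$conc[post]
    for (i in seq_len(length(post) - 1L)) {
      if (cc[i] > 0 && cc[i + 1L] > cc[i] * (1 + config$monotone_rise_frac)) {
        issues[[length(issues) + 1L]] <- validation_issue(
          "warning", "non_monotone_decline",
          sprintf("post-infusion rise %.0f%% between t=%g and t=%g min",
                  100 * (cc[i + 1L] / cc[i] - 1), tt[i], tt[i + 1L]),
          post[i + 1L])
      }
    }
  }
  if (is.finite(profile$assay_lloq)) {
    low <- act[s$conc[act] < profile$assay_lloq]
    for (i in low) {
      issues[[length(issues) + 1L]] <- validation_issue(
        "warning", "below_lloq",
        sprintf("conc %.4g mg/L below LLOQ %.4g mg/L at t=%g min",
                s$conc[i], profile$assay_lloq, s$time[i]), i)
    }
  }
  if (length(issues) == 0L)
    return(validation_issue(character(), character(), character(), integer()))
  do.call(rbind, issues)
}

#' Set or clear the exclusion flag on one sample
#'
#' Exclusion is reversible bookkeeping: the stored time and concentration
#' are untouched, and excluded points never enter any fit, NCA or GOF
#' computation downstream.
#'
#' @param profile A [tdm_profile()].
#' @param sample_index 1-based index into the (time-sorted) sample table.
#' @param excluded Logical flag to set.
#' @param note Free-text reason recorded on the sample.
#' @return The modified profile.
#' @export
set_exclusion <- function(profile, sample_index, excluded, note = "") {
  stopifnot(inherits(profile, "tdm_profile"))
  n <- nrow(profile$samples)
  if (!(sample_index >= 1L && sample_index <= n))
    stop("sample_index out of range [1, ", n, "]", call. = FALSE)
  profile$samples$excluded[sample_index] <- isTRUE(excluded)
  if (nzchar(note)) profile$samples$note[sample_index] <- note
  profile
}

# ---- small accessors shared by the analysis modules ------------------------

#' Non-excluded samples of a profile
#'
#' @param profile A [tdm_profile()].
#' @param post_infusion If `TRUE`, restrict to samples at or after the end
#'   of infusion.
#' @return A `data.frame` of the active samples.
#' @export
active_samples <- function(profile, post_infusion = FALSE) {
  s <- profile$samples[!profile$samples$excluded, , drop = FALSE]
  if (post_infusion)
    s <- s[s$time >= profile$dose$infusion_duration, , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Count of non-excluded samples
#' @rdname active_samples
#' @export
n_active_samples <- function(profile, post_infusion = FALSE) {
  nrow(active_samples(profile, post_infusion))
}
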