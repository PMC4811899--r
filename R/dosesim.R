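# Dose individualization under linear kinetics: per-dose AUC = dose/CL and
# Cavg,ss = AUC/tau are exact steady-state identities (with linear PK the
# steady-state AUC over one interval equals the single-dose AUC to
# infinity), so exposure prediction and dose recommendation are closed-form
# algebra on the patient's clearance.

#' Therapeutic exposure target
#'
#' @param kind One of `"auc_per_dose"` (AUC over one dosing interval at
#'   steady state, canonical mg·min/L), `"cavg_ss"` (average steady-state
#'   concentration, mg/L), `"cumulative_auc"` (total course AUC,
#'   mg·min/L).
#' @param value Target magnitude in `units_in`.
#' @param units_in Unit string: AUC targets accept `mg*min/L`, `mg*h/L`,
#'   `uM*min`, `uM*h`; concentration targets `mg/L`, `ng/mL`, `uM`.
#' @param molar_mass_g_mol Molar mass for micromolar units.
#' @return Object of class `therapeutic_target` with `value` in canonical
#'   units.
#' @export
#' @examples
#' therapeutic_target("auc_per_dose", 1230, "uM*min")
therapeutic_target <- function(kind = c("auc_per_dose", "cavg_ss",
                                        "cumulative_auc"),
                               value, units_in = NULL,
                               molar_mass_g_mol = 246.3) {
  kind <- match.arg(kind)
  if (!(is.numeric(value) && value > 0))
    stop("target value must be > 0", call. = FALSE)
  if (is.null(units_in))
    units_in <- if (kind == "cavg_ss") "mg/L" else "mg*min/L"
  canonical <- target_to_canonical(kind, value, units_in, molar_mass_g_mol)
  structure(list(kind = kind, value = canonical, units_in = units_in,
                 value_in = value),
            class = "therapeutic_target")
}

#' Convert a target value to/from canonical units
#'
#' Canonical units are mg·min/L for AUC-type targets and mg/L for
#' concentration targets. The two functions are exact inverses, so a target
#' entered in, e.g., µM·min round-trips losslessly.
#'
#' @param kind Target kind (see [therapeutic_target()]).
#' @param value Numeric value.
#' @param units_in Unit string.
#' @param molar_mass_g_mol Molar mass for micromolar units (g/mol).
#' @return Converted value.
#' @export
target_to_canonical <- function(kind, value, units_in,
                                molar_mass_g_mol = 246.3) {
  value * .target_unit_factor(kind, units_in, molar_mass_g_mol)
}

#' @rdname target_to_canonical
#' @export
target_from_canonical <- function(kind, value, units_in,
                                  molar_mass_g_mol = 246.3) {
  value / .target_unit_factor(kind, units_in, molar_mass_g_mol)
}

.target_unit_factor <- function(kind, units_in, molar_mass_g_mol) {
  u <- gsub("\\s", "", tolower(units_in))
  u <- gsub("µ", "u", u)
  u <- gsub("\\.", "*", u)
  if (kind == "cavg_ss") {
    switch(u,
      "mg/l"  = 1,
      "ug/ml" = 1,
      "ng/ml" = 1e-3,
      "umol/l" = ,
      "um"    = molar_mass_g_mol / 1000,
      stop("unknown concentration unit: ", units_in, call. = FALSE))
  } else {
    switch(u,
      "mg*min/l" = 1,
      "mg*h/l"   = 60,
      "umol*min/l" = ,
      "um*min"   = molar_mass_g_mol / 1000,
      "umol*h/l" = ,
      "um*h"     = 60 * molar_mass_g_mol / 1000,
      stop("unknown AUC unit: ", units_in, call. = FALSE))
  }
}

#' Dosing regimen for simulation
#'
#' @param current_dose Dose (mg) given from dose 1 up to the change point.
#' @param tau Dosing interval (min).
#' @param total_doses Planned doses in the course.
#' @param change_at Dose number at which the regimen changes (must follow
#'   the studied dose).
#' @param studied_dose_number Dose number of the TDM study (default 1).
#' @return A `regimen` list.
#' @export
regimen <- function(current_dose, tau, total_doses, change_at,
                    studied_dose_number = 1L) {
  stopifnot(current_dose > 0, tau > 0)
  change_at <- as.integer(change_at)
  total_doses <- as.integer(total_doses)
  if (change_at < studied_dose_number + 1L)
    stop("change_at must be at least the studied dose number + 1",
         call. = FALSE)
  if (change_at > total_doses)
    stop("change_at cannot exceed total_doses", call. = FALSE)
  structure(list(current_dose = current_dose, tau = tau,
                 total_doses = total_doses, change_at = change_at,
                 studied_dose_number = as.integer(studied_dose_number)),
            class = "regimen")
}

#' Predicted steady-state exposure for a dose
#'
#' @param CL Clearance (L/min).
#' @param dose Dose per administration (mg).
#' @param tau Dosing interval (min).
#' @return List of class `exposure_summary`: `auc_per_dose` (mg·min/L),
#'   `cavg_ss` (mg/L), `cumulative_auc` (`NA` without a regimen; see
#'   [exposure_for_dose()]).
#' @export
#' @examples
#' predict_exposure(0.25, 100, 360)
predict_exposure <- function(CL, dose, tau) {
  stopifnot(CL > 0, dose > 0, tau > 0)
  auc <- dose / CL
  structure(list(auc_per_dose = auc, cavg_ss = auc / tau,
                 cumulative_auc = NA_real_),
            class = "exposure_summary")
}

#' Exposure summary for a trial dose under a change schedule
#'
#' Cumulative AUC sums per-dose AUCs over the whole course: doses before
#' `change_at` at the current dose, doses from `change_at` on at the trial
#' dose.
#'
#' @param CL Clearance (L/min).
#' @param trial_dose Dose (mg) from the change point onward.
#' @param reg A [regimen()].
#' @return An `exposure_summary` with `cumulative_auc` filled in.
#' @export
exposure_for_dose <- function(CL, trial_dose, reg) {
  stopifnot(inherits(reg, "regimen"), trial_dose > 0, CL > 0)
  out <- predict_exposure(CL, trial_dose, reg$tau)
  n_before <- reg$change_at - 1L
  n_after <- reg$total_doses - reg$change_at + 1L
  out$cumulative_auc <- n_before * reg$current_dose / CL +
    n_after * trial_dose / CL
  out
}

#' Recommend a dose to hit a therapeutic target
#'
#' Closed-form inversion of the linear-PK exposure identities:
#' \itemize{
#'   \item AUC-per-dose target \eqn{T}: dose \eqn{= CL \cdot T};
#'   \item Cavg,ss target \eqn{T}: dose \eqn{= CL \cdot T \cdot \tau};
#'   \item cumulative-AUC target \eqn{T}: dose
#'     \eqn{= CL (T - (n_{change}-1) D_{cur}/CL) / (n_{tot} - n_{change} +
#'     1)}, erroring with `target_already_exceeded` when the doses already
#'     planned at the current dose meet or exceed the target.
#' }
#' Rounded what-if variants on the configured grid (default 5 mg) are
#' reported with their resulting exposures.
#'
#' @param CL Patient clearance (L/min), from the accepted compartmental fit
#'   or NCA.
#' @param target A [therapeutic_target()].
#' @param reg A [regimen()].
#' @param config An `analysis_config` (`dose_rounding_mg`).
#' @param dosing_weight Optional weight (kg) for the informational mg/kg
#'   rendering.
#' @return Object of class `dose_recommendation`: `current_dose`,
#'   `recommended_dose` (mg), `change_at_dose_number`, `total_doses`,
#'   `clearance_CL`, `target`, `predicted` (`exposure_summary` at the
#'   recommended dose), `rounded_variants` (list of dose + exposure).
#' @export
#' @examples
#' reg <- regimen(current_dose = 100, tau = 360, total_doses = 16,
#'                change_at = 9, studied_dose_number = 5)
#' recommend_dose(0.25, therapeutic_target("cumulative_auc", 5600), reg)
recommend_dose <- function(CL, target, reg, config = default_config(),
                           dosing_weight = NA_real_) {
  stopifnot(inherits(target, "therapeutic_target"), inherits(reg, "regimen"),
            CL > 0)
  dose <- switch(target$kind,
    auc_per_dose = CL * target$value,
    cavg_ss      = CL * target$value * reg$tau,
    cumulative_auc = {
      remaining <- target$value - (reg$change_at - 1L) * reg$current_dose / CL
      if (remaining <= 0)
        stop(structure(
          class = c("bustdm_target_exceeded", "error", "condition"),
          list(message = paste0(
            "target_already_exceeded: planned exposure before the change (",
            format((reg$change_at - 1L) * reg$current_dose / CL),
            " mg*min/L) meets or exceeds the cumulative target"),
            call = NULL)))
      CL * remaining / (reg$total_doses - reg$change_at + 1L)
    })
  grid <- config$dose_rounding_mg
  lo <- floor(dose / grid) * grid
  hi <- ceiling(dose / grid) * grid
  rounded <- unique(c(lo, hi))
  rounded <- rounded[rounded > 0]
  variants <- lapply(rounded, function(d)
    list(dose = d, exposure = exposure_for_dose(CL, d, reg)))
  structure(list(
    current_dose = reg$current_dose,
    recommended_dose = dose,
    recommended_dose_per_kg = dose / dosing_weight,
    change_at_dose_number = reg$change_at,
    total_doses = reg$total_doses,
    clearance_CL = CL,
    target = target,
    predicted = exposure_for_dose(CL, dose, reg),
    rounded_variants = variants
  ), class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("<dose_recommendation> %.1f mg (current %.1f mg), change at dose %d of %d\n",
              x$recommended_dose, x$current_dose, x$change_at_dose_number,
              x$total_doses))
  cat(sprintf("  target %s = %g (%s); CL = %.4g L/min\n", x$target$kind,
              x$target$value_in, x$target$units_in, x$clearance_CL))
  cat(sprintf("  predicted AUC/dose %.1f mg*min/L, Cavg,ss %.3f mg/L, cumulative AUC %.0f mg*min/L\n",
              x$predicted$auc_per_dose, x$predicted$cavg_ss,
              x$predicted$cumulative_auc))
  for (v in x$rounded_variants)
    cat(sprintf("  rounded %.0f mg -> AUC/dose %.1f, cumulative %.0f mg*min/L\n",
                v$dose, v$exposure$auc_per_dose, v$exposure$cumulative_auc))
  invisible(x)
}
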