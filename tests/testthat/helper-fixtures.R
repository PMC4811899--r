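# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# Exact (noise-free) one-compartment profile on the given sampling times.
make_profile_1cpt <- function(CL = 0.25, V = 50, dose_mg = 100, tinf = 120,
                              tau = 360, times = c(135, 150, 180, 240, 360),
                              patient_id = "fix-1cpt", weight = 30,
                              dose_number = 1L, total_doses = 16L) {
  dose <- infusion_event(dose_mg, tinf, tau, dose_number, total_doses)
  p <- onecpt_params(CL, V)
  tdm_profile(patient_id, weight, dose,
              data.frame(time = times, conc = conc_onecpt(times, p, dose)))
}

# Exact two-compartment profile from micro-constants.
make_profile_2cpt <- function(V1 = 20, k10 = 0.006, k12 = 0.02, k21 = 0.02,
                              dose_mg = 100, tinf = 120, tau = 360,
                              times = c(125, 135, 150, 180, 240, 300, 360),
                              patient_id = "fix-2cpt", weight = 30) {
  dose <- infusion_event(dose_mg, tinf, tau)
  p <- twocpt_params(V1, k10, k12, k21)
  tdm_profile(patient_id, weight, dose,
              data.frame(time = times, conc = conc_twocpt(times, p, dose)))
}

# Standard-schema CSV fixture; returns the path.
write_csv_fixture <- function(path = tempfile(fileext = ".csv"),
                              conc = c(4.2, 2.1, 0.9),
                              conc_unit = "mg/L",
                              excluded = c(FALSE, FALSE, FALSE)) {
  df <- data.frame(patient_id = "pt-001", dosing_weight_kg = 28.5,
                   dose_mg = 100, infusion_duration_min = 120, tau_min = 360,
                   dose_number = 5, total_doses = 16,
                   sample_time_min = c(135, 240, 360), conc = conc,
                   conc_unit = conc_unit, excluded = excluded,
                   note = c("", "", ""))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Every reason code the pipeline can emit.
.all_reason_codes <- c("few_points_1cpt_only", "no_2cpt_candidate",
                       "accepted_2cpt", "rejected_2cpt", "no_converged_fit",
                       "high_param_cv", "non_monotone_red_fit",
                       "user_override")

# Deterministic sub-seed for replicate loops in tests.
.derive_fixture_seed <- function(seed, i) (seed * 1009L + i * 13L) %% 2147483647L

# Densely sampled noise-free population (during-infusion points included so
# the trapezoid grid tracks the infusion rise).
dense_noisefree_pop <- function(...) {
  default_population(prop_noise_cv = 0, add_noise_sd = 0,
                     schedule = c(15, 30, 45, 60, 90, 120, 135, 150, 180,
                                  240, 300, 360, 420, 480), ...)
}
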