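# Analysis configuration: every tunable threshold of the pipeline lives here
# so site policies can be swapped without touching code.

#' Default analysis configuration
#'
#' Returns the full set of tunable thresholds used by the fitting,
#' model-selection, goodness-of-fit, NCA and dose-simulation machinery.
#' Every entry can be overridden via [read_config()] or by modifying the
#' returned list.
#'
#' @details
#' Key groups:
#' \describe{
#'   \item{weighting}{`weighting_scheme` one of `"one_over_pred_sq"`
#'     (iteratively reweighted \eqn{1/\hat{C}^2}, the default),
#'     `"one_over_obs_sq"`, `"one_over_obs"`, `"unweighted"`;
#'     `weight_floor` (mg/L) guards the denominator.}
#'   \item{selection}{`min_points_2cpt` (post-infusion points required before
#'     a two-compartment fit is attempted), `cv_accept_2cpt` (max CV\% for
#'     accepting the richer model), `eigenratio_min` (required
#'     \eqn{\alpha/\beta}), `ftest_alpha` (extra-sum-of-squares F-test
#'     level), `cv_fallback` (CV\% at or above which the accepted fit is
#'     abandoned for NCA).}
#'   \item{gof}{reference values, log-slope, component weights and band
#'     cut-points of the 10-point score.}
#'   \item{units}{`molar_mass_g_mol`, used for micromolar conversions
#'     (busulfan 246.3 g/mol).}
#' }
#'
#' @return A named list of class `analysis_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$ftest_alpha
default_config <- function() {
  structure(list(
    # -- weighting / fitting --
    weighting_scheme = "one_over_pred_sq",
    weight_floor     = 0.01,    # mg/L
    irls_passes      = 3L,
    max_iterations   = 200L,
    ptol             = 1e-8,    # relative parameter-change tolerance
    ftol             = 1e-10,   # relative SS-change tolerance
    # -- nested model selection --
    min_points_2cpt  = 5L,
    cv_accept_2cpt   = 50,      # %
    eigenratio_min   = 2,
    ftest_alpha      = 0.05,
    use_aicc         = FALSE,   # alternative discriminator to the F-test
    cv_fallback      = 100,     # %
    # -- GOF tachometer --
    gof_ref_rmse_frac = 0.10,
    gof_ref_cv        = 25,     # %
    gof_slope         = 3,
    gof_eps           = 1e-12,
    gof_band_green    = 7.0,
    gof_band_yellow   = 4.0,
    gof_weights       = NULL,   # NULL = equal weights over components
    # -- validation --
    min_post_infusion_points = 3L,
    monotone_rise_frac       = 0.20,
    # -- NCA --
    nca_extrap_flag     = 0.20,
    nca_r2_flag         = 0.95,
    nca_use_pred_clast  = TRUE,
    # -- dose simulation --
    dose_rounding_mg    = 5,
    # -- units / registry --
    molar_mass_g_mol    = 246.3,
    registry_key        = "patient_study"  # or "patient_only"
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Values found in the file override the defaults from [default_config()];
#' unknown keys are rejected so typos surface immediately.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext, call. = FALSE))
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  cfg
}

#' Deterministic digest of an analysis configuration
#'
#' Reports embed this digest so a reviewer can tell which thresholds were in
#' force. Computed as the MD5 of the canonical (alphabetically keyed) JSON
#' rendering of the configuration.
#'
#' @param config An `analysis_config` list.
#' @return A 32-character hex string.
#' @export
config_digest <- function(config = default_config()) {
  cfg <- config[order(names(config))]
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = I(17), null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(txt), tf)
  unname(tools::md5sum(tf))
}
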