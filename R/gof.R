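# Goodness-of-fit tachometer: collapse quantitative fit-quality criteria
# (weighted residual magnitude, parameter CVs on the coefficient/exponent
# scale) into a single 0-10 score banded green/yellow/red for
# non-specialist users.

#' Goodness-of-fit component metrics
#'
#' Extracts the raw ingredients of the tachometer score from a fit:
#' the weighted RMSE expressed as a fraction of the weighted mean observed
#' concentration, and the CV\% of each coefficient and exponent (macro
#' scale).
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param profile The [tdm_profile()] the fit was computed on.
#' @return List of class `gof_components`: `weighted_rmse_frac`,
#'   `cv_coefficients` (\%), `cv_exponents` (\%).
#' @export
gof_components <- function(fit, profile) {
  stopifnot(inherits(fit, "fit_result"), inherits(profile, "tdm_profile"))
  m <- fit$n_obs
  if (m == 0L) stop("fit has no observations", call. = FALSE)
  wmean <- sum(fit$weights * fit$obs_conc) / sum(fit$weights)
  rmse_frac <- sqrt(fit$weighted_SS / m) / wmean
  cvs <- fit$macro_cv
  if (fit$model_order == 1L) {
    coef_cv <- cvs["B"]; exp_cv <- cvs["lambda"]
  } else {
    coef_cv <- cvs[c("A", "B")]; exp_cv <- cvs[c("alpha", "beta")]
  }
  structure(list(weighted_rmse_frac = unname(rmse_frac),
                 cv_coefficients = unname(coef_cv),
                 cv_exponents = unname(exp_cv)),
            class = "gof_components")
}

#' Collapse fit-quality components to the 10-point tachometer score
#'
#' Each component metric \eqn{m_j} is log-adjusted against its reference
#' value and clamped:
#' \deqn{s_j = \mathrm{clamp}(10 - c \cdot \log_{10}(\max(m_j,
#'   \epsilon)/\mathrm{ref}_j),\; 0,\; 10)}
#' so a component at its reference scores 10 and one at ten times the
#' reference scores \eqn{10 - c} (7 with the default slope). The overall
#' score is the weighted mean of the component scores (equal weights by
#' default). Bands: green for score \eqn{\ge} 7.0, yellow for
#' \eqn{[4.0, 7.0)}, red below 4.0. "Green" signals a strong model,
#' "yellow" caution, "red" a likely problem with the fit.
#'
#' @param components A `gof_components` (entries may be `Inf` for
#'   rank-deficient fits; such components score 0).
#' @param config An `analysis_config` (references `gof_ref_rmse_frac`,
#'   `gof_ref_cv`, slope `gof_slope`, `gof_weights`, band cut-points).
#' @return List of class `gof_score`: `component_scores`, `score` in
#'   \[0, 10\], `band` in \{green, yellow, red\}.
#' @export
#' @examples
#' comp <- structure(list(weighted_rmse_frac = 0.1, cv_coefficients = 25,
#'                        cv_exponents = 25), class = "gof_components")
#' gof_score(comp)$score  # every component at its reference: 10
gof_score <- function(components, config = default_config()) {
  stopifnot(inherits(components, "gof_components"))
  metrics <- c(rmse_frac = components$weighted_rmse_frac,
               stats::setNames(components$cv_coefficients,
                 paste0("cv_coef", seq_along(components$cv_coefficients))),
               stats::setNames(components$cv_exponents,
                 paste0("cv_exp", seq_along(components$cv_exponents))))
  refs <- c(config$gof_ref_rmse_frac,
            rep(config$gof_ref_cv, length(metrics) - 1L))
  ratio <- pmax(metrics, config$gof_eps) / refs
  s <- pmin(pmax(10 - config$gof_slope * log10(ratio), 0), 10)
  s[!is.finite(metrics)] <- 0  # +Inf sentinel (rank-deficient CVs)
  w <- config$gof_weights
  if (is.null(w)) w <- rep(1, length(s))
  score <- sum(w * s) / sum(w)
  band <- if (score >= config$gof_band_green) "green"
          else if (score >= config$gof_band_yellow) "yellow"
          else "red"
  structure(list(component_scores = unname(s), score = score, band = band),
            class = "gof_score")
}

#' @export
print.gof_score <- function(x, ...) {
  cat(sprintf("<gof_score> %.1f/10 (%s)\n", x$score, x$band))
  invisible(x)
}
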