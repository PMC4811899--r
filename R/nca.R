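# Non-compartmental (model-independent) analysis: terminal slope by
# best-adjusted-r2 log-linear regression, linear-up/log-down trapezoidal
# AUC with monoexponential extrapolation, and clearance.

.nca_error <- function(msg) {
  stop(structure(class = c("bustdm_nca_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Terminal elimination rate constant (lambda-z)
#'
#' Among candidate terminal windows (the last \eqn{k} non-excluded positive
#' concentrations from the observed peak onward, \eqn{k = 3} up to all),
#' selects the window maximizing the adjusted \eqn{r^2} of the log-linear
#' regression; exact ties resolve toward the larger window. The slope must
#' be negative.
#'
#' @param profile A [tdm_profile()] with at least 3 non-excluded positive
#'   post-peak concentrations.
#' @return List: `lambda_z` (1/min), `r2_adj`, `n_terminal`, `intercept`
#'   (log mg/L at t = 0), `t_last`, `clast_obs`, `clast_pred` (regression-
#'   predicted concentration at the last sample time).
#' @export
#' @examples
#' p <- tdm_profile("x", 30, infusion_event(100, 120, 360),
#'                  data.frame(time = c(120, 180, 240), conc = c(8, 4, 2)))
#' lambda_z(p)$lambda_z  # ln(2)/60
lambda_z <- function(profile) {
  stopifnot(inherits(profile, "tdm_profile"))
  s <- active_samples(profile)
  s <- s[s$conc > 0, , drop = FALSE]
  if (nrow(s) < 3L)
    .nca_error("need >= 3 non-excluded positive concentrations")
  i_max <- which.max(s$conc)
  pool <- s[seq.int(i_max, nrow(s)), , drop = FALSE]
  n <- nrow(pool)
  if (n < 3L)
    .nca_error("no declining terminal phase: peak at or near the last sample")
  best <- NULL
  for (k in 3:n) {
    win <- pool[seq.int(n - k + 1L, n), , drop = FALSE]
    if (length(unique(win$time)) < 2L) next
    fit <- stats::lm(log(win$conc) ~ win$time)
    slope <- unname(stats::coef(fit)[2L])
    if (!is.finite(slope) || slope >= 0) next
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact data warns
    r2_adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || r2_adj >= best$r2_adj - 1e-9) {
      best <- list(lambda_z = -slope, r2_adj = r2_adj, n_terminal = k,
                   intercept = unname(stats::coef(fit)[1L]))
    }
  }
  if (is.null(best))
    .nca_error("no declining terminal phase found (slope >= 0)")
  t_last <- s$time[nrow(s)]
  best$t_last <- t_last
  best$clast_obs <- s$conc[nrow(s)]
  best$clast_pred <- exp(best$intercept - best$lambda_z * t_last)
  best
}

#' Trapezoidal AUC to the last sample (linear-up/log-down)
#'
#' An implicit anchor (0 min, 0 mg/L) at infusion start is always
#' prepended. Ascending segments (and any segment touching a zero
#' concentration) use the linear trapezoid; descending segments use the
#' logarithmic trapezoid \eqn{(t_2 - t_1)(C_1 - C_2)/\ln(C_1/C_2)}, which is
#' exact for a monoexponential through the two points.
#'
#' @param profile A [tdm_profile()] with at least 2 non-excluded samples.
#' @return `auc_last` (mg·min/L).
#' @export
auc_trapezoid <- function(profile) {
  stopifnot(inherits(profile, "tdm_profile"))
  s <- active_samples(profile)
  if (nrow(s) < 2L)
    .nca_error("need >= 2 non-excluded samples for the trapezoid")
  t <- c(0, s$time)
  cc <- c(0, s$conc)
  auc <- 0
  for (i in seq_len(length(t) - 1L)) {
    dt <- t[i + 1L] - t[i]
    c1 <- cc[i]; c2 <- cc[i + 1L]
    piece <- if (c2 >= c1 || c1 == 0 || c2 == 0) {
      dt * (c1 + c2) / 2
    } else {
      dt * (c1 - c2) / log(c1 / c2)
    }
    auc <- auc + piece
  }
  auc
}

#' Full non-compartmental analysis of a profile
#'
#' Combines [lambda_z()] and [auc_trapezoid()]:
#' \eqn{AUC_{0-\infty} = AUC_{last} + C_{last}/\lambda_z}, with
#' \eqn{C_{last}} the regression-predicted (default) or observed last
#' concentration, and \eqn{CL = D / AUC_{0-\infty}}. Quality flags:
#' `high_extrapolation` when the extrapolated fraction exceeds
#' `nca_extrap_flag` (default 20\%), `few_terminal_points` when only 3
#' terminal points were used with adjusted \eqn{r^2 <} `nca_r2_flag`.
#'
#' @param profile A [tdm_profile()].
#' @param config An `analysis_config`.
#' @return Object of class `nca_result`: `lambda_z`, `lambda_z_r2_adj`,
#'   `n_terminal`, `auc_last`, `auc_inf` (mg·min/L), `extrap_fraction`,
#'   `clearance_CL` (L/min), `flags`.
#' @export
nca_analyze <- function(profile, config = default_config()) {
  lam <- lambda_z(profile)
  auc_last <- auc_trapezoid(profile)
  clast <- if (isTRUE(config$nca_use_pred_clast)) lam$clast_pred
           else lam$clast_obs
  auc_inf <- auc_last + clast / lam$lambda_z
  extrap <- (auc_inf - auc_last) / auc_inf
  flags <- character(0)
  if (extrap > config$nca_extrap_flag) flags <- c(flags, "high_extrapolation")
  if (lam$n_terminal == 3L && lam$r2_adj < config$nca_r2_flag)
    flags <- c(flags, "few_terminal_points")
  structure(list(lambda_z = lam$lambda_z,
                 lambda_z_r2_adj = lam$r2_adj,
                 n_terminal = lam$n_terminal,
                 auc_last = auc_last,
                 auc_inf = auc_inf,
                 extrap_fraction = extrap,
                 clearance_CL = profile$dose$dose_amount / auc_inf,
                 flags = flags),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> lambda_z=%.5g /min (adj r2 %.4f, n=%d)\n",
              x$lambda_z, x$lambda_z_r2_adj, x$n_terminal))
  cat(sprintf("  AUC_last=%.4g, AUC_inf=%.4g mg*min/L (%.1f%% extrapolated)\n",
              x$auc_last, x$auc_inf, 100 * x$extrap_fraction))
  cat(sprintf("  CL=%.4g L/min%s\n", x$clearance_CL,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}
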