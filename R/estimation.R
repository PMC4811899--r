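# Curve-stripping initial estimates, weighted Levenberg-Marquardt fitting,
# and the nested model-selection logic with non-compartmental fallback.
#
# Fitting parameterization: all model parameters are strictly positive, so
# the optimizer works on log-parameters. Residuals are weighted; the default
# scheme is predicted-value weighting 1/max(Chat, floor)^2, iteratively
# reweighted over a fixed number of outer passes so the fit is deterministic.

.strip_error <- function(msg) {
  stop(structure(class = c("bustdm_strip_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Curve-stripping (method of residuals) initial estimates
#'
#' Peels exponential phases off the post-infusion decline to initialize the
#' nonlinear fit. A log-linear regression on the last `n_terminal` points
#' (3 by default; the last half, rounded up, when more than 6 post-infusion
#' points are available) gives the terminal intercept `B` and slope
#' `lambda`; residuals of the earlier points against that terminal line,
#' when at least two are strictly positive, yield a second phase `(A,
#' alpha)` by another log-linear regression. Times are measured from the end
#' of infusion, so `B` estimates the end-of-infusion concentration.
#'
#' @param profile A [tdm_profile()] with at least 3 positive non-excluded
#'   post-infusion concentrations.
#' @return List of class `stripping_estimate`: `candidate_1cpt` (`B` mg/L,
#'   `lambda` 1/min), `candidate_2cpt` (`A`, `alpha`, `B`, `beta`, or `NULL`
#'   when no second phase emerges), `n_terminal`, `terminal_r2`.
#' @export
strip_estimates <- function(profile) {
  stopifnot(inherits(profile, "tdm_profile"))
  post <- active_samples(profile, post_infusion = TRUE)
  m <- nrow(post)
  if (m < 3L)
    stop("need >= 3 non-excluded post-infusion samples for stripping",
         call. = FALSE)
  tp <- post$time - profile$dose$infusion_duration
  cc <- post$conc
  # > 6 points: strip the last half (keeping the earlier half for the fast
  # phase); an odd count leaves the middle point with the fast phase
  n_term <- if (m > 6L) max(3L, as.integer(floor(m / 2))) else 3L
  idx_term <- seq.int(m - n_term + 1L, m)
  if (any(cc[idx_term] <= 0))
    .strip_error("non-positive concentration among terminal regression points")
  fit_term <- stats::lm(log(cc[idx_term]) ~ tp[idx_term])
  slope <- unname(stats::coef(fit_term)[2L])
  if (!is.finite(slope) || slope >= 0)
    .strip_error("terminal phase not declining (slope >= 0)")
  lambda <- -slope
  B <- exp(unname(stats::coef(fit_term)[1L]))
  r2 <- suppressWarnings(summary(fit_term)$r.squared)  # exact data warns
  candidate_2 <- NULL
  idx_early <- seq_len(m - n_term)
  if (length(idx_early) > 0L) {
    resid <- cc[idx_early] - B * exp(-lambda * tp[idx_early])
    pos <- which(resid > 0)
    if (length(pos) >= 2L && length(unique(tp[idx_early][pos])) >= 2L) {
      fit_a <- stats::lm(log(resid[pos]) ~ tp[idx_early][pos])
      sa <- unname(stats::coef(fit_a)[2L])
      if (is.finite(sa) && sa < 0 && -sa > lambda) {
        candidate_2 <- list(A = exp(unname(stats::coef(fit_a)[1L])),
                            alpha = -sa, B = B, beta = lambda)
      }
    }
  }
  structure(list(candidate_1cpt = list(B = B, lambda = lambda),
                 candidate_2cpt = candidate_2,
                 n_terminal = n_term, terminal_r2 = r2),
            class = "stripping_estimate")
}

# Map stripped macro estimates to model parameters usable as LM starting
# values. The stripped intercepts describe the post-infusion curve; the
# factor lambda*Tinf/(1 - exp(-lambda*Tinf)) converts each to its
# bolus-equivalent intercept before the standard micro-constant algebra.
.init_onecpt <- function(strip, dose) {
  k <- strip$candidate_1cpt$lambda
  B <- strip$candidate_1cpt$B
  r0 <- dose$dose_amount / dose$infusion_duration
  cl <- r0 * (1 - exp(-k * dose$infusion_duration)) / B
  onecpt_params(cl, cl / k)
}

.init_twocpt <- function(strip, dose) {
  cand <- strip$candidate_2cpt
  if (is.null(cand))
    stop("no two-compartment stripping candidate available", call. = FALSE)
  tinf <- dose$infusion_duration
  infusion_corr <- function(coef, lambda)
    coef * lambda * tinf / (1 - exp(-lambda * tinf))
  Ab <- infusion_corr(cand$A, cand$alpha)
  Bb <- infusion_corr(cand$B, cand$beta)
  alpha <- cand$alpha; beta <- cand$beta
  k21 <- (Ab * beta + Bb * alpha) / (Ab + Bb)
  k10 <- alpha * beta / k21
  k12 <- alpha + beta - k10 - k21
  if (!is.finite(k12) || k12 <= 0) k12 <- 0.1 * k10  # degenerate strip: nudge
  V1 <- dose$dose_amount / (Ab + Bb)
  twocpt_params(V1, k10, k12, k21)
}

.theta_from_params <- function(params) {
  if (inherits(params, "onecpt_params")) log(c(params$CL, params$V))
  else log(c(params$V1, params$k10, params$k12, params$k21))
}

.params_from_theta <- function(theta, order) {
  v <- exp(pmin(pmax(theta, -40), 40))
  if (order == 1L) onecpt_params(v[1L], v[2L])
  else twocpt_params(v[1L], v[2L], v[3L], v[4L])
}

# Macro-scale parameter vector (the "coefficients and exponents" whose CVs
# feed the GOF score). Order 1: end-of-infusion intercept B and slope
# lambda; order 2: A, B, alpha, beta.
.macro_vector <- function(theta, order, dose) {
  params <- .params_from_theta(theta, order)
  if (order == 1L) {
    c(B = unname(conc_onecpt(dose$infusion_duration, params, dose)),
      lambda = params$k)
  } else {
    mac <- macro_from_micro(params)
    c(A = mac$A, B = mac$B, alpha = mac$alpha, beta = mac$beta)
  }
}

.weights_for <- function(scheme, obs, pred, floor) {
  switch(scheme,
    one_over_pred_sq = 1 / pmax(pred, floor)^2,
    one_over_obs_sq  = 1 / pmax(obs, floor)^2,
    one_over_obs     = 1 / pmax(obs, floor),
    unweighted       = rep(1, length(obs)),
    stop("unknown weighting scheme: ", scheme, call. = FALSE))
}

.num_jacobian <- function(fn, theta, eps = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(NA_real_, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * max(1, abs(theta[j]))
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

#' Fit a compartmental model by weighted Levenberg-Marquardt
#'
#' Minimizes the weighted residual sum of squares
#' \eqn{\sum_i w_i (C_i - \hat{C}(t_i; \theta))^2} over log-transformed
#' parameters (positivity without box constraints) using the
#' Levenberg-Marquardt algorithm. Under the default predicted-value
#' weighting \eqn{w_i = 1/\max(\hat{C}_i, floor)^2} the weights are frozen
#' and refreshed over `irls_passes` outer passes. Parameter CV\% come from
#' the scaled covariance (inverse Gauss-Newton Hessian at the optimum) and
#' are propagated to the macro scale (intercepts/exponents) by the delta
#' method. During-infusion samples, if present, enter the objective with
#' the same weighting.
#'
#' @param profile A [tdm_profile()] passing [validate_profile()] without
#'   errors.
#' @param order Model order, 1 or 2.
#' @param init A [strip_estimates()] result, or `NULL` to strip internally,
#'   or a `onecpt_params`/`twocpt_params` start directly.
#' @param config An `analysis_config` (weighting scheme, tolerances,
#'   iteration cap).
#' @return Object of class `fit_result`: `model_order`, `params`, `macro`
#'   (values on the coefficient/exponent scale), `predictions` (aligned
#'   1:1 with non-excluded samples), `weights`, `weighted_SS`,
#'   `param_cv` (micro scale) and `macro_cv` (\%), `converged`,
#'   `n_iterations`, `rss_trace` (accepted-step objective values, one vector
#'   per reweighting pass; the weights, and hence the objective scale, are
#'   fixed within a pass).
#' @export
fit_model <- function(profile, order, init = NULL, config = default_config()) {
  stopifnot(inherits(profile, "tdm_profile"), order %in% c(1L, 2L))
  order <- as.integer(order)
  obs <- active_samples(profile)
  t <- obs$time; y <- obs$conc
  m <- length(y)
  dose <- profile$dose
  if (inherits(init, c("onecpt_params", "twocpt_params"))) {
    start <- init
  } else {
    strip <- if (inherits(init, "stripping_estimate")) init
             else strip_estimates(profile)
    start <- if (order == 1L) .init_onecpt(strip, dose)
             else .init_twocpt(strip, dose)
  }
  theta <- .theta_from_params(start)
  predict_fn <- function(th) conc_model(t, .params_from_theta(th, order), dose)

  scheme <- config$weighting_scheme
  n_pass <- if (scheme == "one_over_pred_sq") config$irls_passes else 1L
  w <- .weights_for(scheme, y, predict_fn(theta), config$weight_floor)
  total_iter <- 0L
  rss_trace <- list()  # accepted-step objective values, one entry per pass
  converged <- FALSE
  for (pass in seq_len(n_pass)) {
    res_fn <- local({
      w_fix <- w
      function(th) sqrt(w_fix) * (y - predict_fn(th))
    })
    lm_fit <- minpack.lm::nls.lm(
      par = theta, fn = res_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = min(config$max_iterations, 1024L),
        ptol = config$ptol, ftol = config$ftol))
    theta <- lm_fit$par
    total_iter <- total_iter + lm_fit$niter
    rss_trace[[pass]] <- lm_fit$rsstrace
    # info 1-3: ftol/ptol criteria met; 4: gradient orthogonal to residual
    # (reached, e.g., at an exact-data zero-residual optimum)
    converged <- lm_fit$info %in% 1:4
    if (scheme == "one_over_pred_sq")
      w <- .weights_for(scheme, y, predict_fn(theta), config$weight_floor)
  }
  pred <- predict_fn(theta)
  wres <- sqrt(w) * (y - pred)
  wss <- sum(wres^2)
  p <- length(theta)

  # covariance on the log-parameter scale; sd(log theta) ~ relative sd
  J <- .num_jacobian(function(th) sqrt(w) * (y - predict_fn(th)), theta)
  sigma2 <- if (m > p) wss / (m - p) else NA_real_
  cov_theta <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  rank_deficient <- is.null(cov_theta) ||
    any(!is.finite(diag(cov_theta))) || any(diag(cov_theta) < 0)
  micro_names <- if (order == 1L) c("CL", "V") else c("V1", "k10", "k12", "k21")
  macro_val <- .macro_vector(theta, order, dose)
  if (rank_deficient) {
    cv_micro <- stats::setNames(rep(Inf, p), micro_names)
    cv_macro <- stats::setNames(rep(Inf, length(macro_val)), names(macro_val))
  } else {
    cv_micro <- stats::setNames(100 * sqrt(pmax(diag(cov_theta), 0)),
                                micro_names)
    G <- .num_jacobian(function(th) .macro_vector(th, order, dose), theta)
    cov_macro <- G %*% cov_theta %*% t(G)
    cv_macro <- stats::setNames(
      100 * sqrt(pmax(diag(cov_macro), 0)) / pmax(abs(macro_val), 1e-300),
      names(macro_val))
  }
  structure(list(
    model_order = order,
    params = .params_from_theta(theta, order),
    macro = as.list(macro_val),
    predictions = pred,
    obs_times = t,
    obs_conc = y,
    weights = w,
    weighted_SS = wss,
    n_obs = m,
    n_par = p,
    param_cv = cv_micro,
    macro_cv = cv_macro,
    rank_deficient = rank_deficient,
    converged = converged,
    n_iterations = total_iter,
    rss_trace = rss_trace
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d-compartment, converged=%s, WSS=%.4g (%d obs)\n",
              x$model_order, x$converged, x$weighted_SS, x$n_obs))
  if (x$model_order == 1L)
    cat(sprintf("  CL=%.4g L/min (CV %.1f%%), V=%.4g L (CV %.1f%%)\n",
                x$params$CL, x$param_cv["CL"], x$params$V, x$param_cv["V"]))
  else
    cat(sprintf("  V1=%.4g L, k10=%.4g, k12=%.4g, k21=%.4g /min; CL=%.4g L/min\n",
                x$params$V1, x$params$k10, x$params$k12, x$params$k21,
                x$params$CL))
  invisible(x)
}

# Extra-sum-of-squares F-test of the 2-compartment model against the nested
# 1-compartment model; both fits must use the same weighting scheme.
.ftest_p <- function(fit1, fit2) {
  df1 <- fit2$n_par - fit1$n_par
  df2 <- fit2$n_obs - fit2$n_par
  if (df2 <= 0 || fit2$weighted_SS >= fit1$weighted_SS) return(1)
  fstat <- ((fit1$weighted_SS - fit2$weighted_SS) / df1) /
    (fit2$weighted_SS / df2)
  stats::pf(fstat, df1, df2, lower.tail = FALSE)
}

.aicc <- function(fit) {
  m <- fit$n_obs; p <- fit$n_par + 1  # + residual variance
  if (m - p - 1 <= 0) return(Inf)
  m * log(fit$weighted_SS / m) + 2 * p + 2 * p * (p + 1) / (m - p - 1)
}

#' Nested model selection with non-compartmental fallback
#'
#' Implements the decision cascade choosing between one- and two-compartment
#' fits and the model-independent (NCA) route:
#' \enumerate{
#'   \item fewer than `min_points_2cpt` post-infusion points: fit the
#'     one-compartment model only;
#'   \item otherwise, when stripping produces a biexponential candidate, fit
#'     both orders and accept the two-compartment model only if it
#'     converged, every coefficient/exponent CV is below `cv_accept_2cpt`,
#'     \eqn{\alpha/\beta \ge} `eigenratio_min`, and the extra-sum-of-squares
#'     F-test rejects the one-compartment model at `ftest_alpha`;
#'   \item fall back to NCA when no compartmental fit converged
#'     (`no_converged_fit`), the accepted fit carries a parameter CV at or
#'     above `cv_fallback` (`high_param_cv`), or the profile showed a
#'     non-monotone post-infusion decline and the accepted fit's tachometer
#'     band is red (`non_monotone_red_fit`).
#' }
#' All thresholds live in the configuration; the cascade itself is fixed.
#'
#' @param profile A [tdm_profile()].
#' @param config An `analysis_config`.
#' @return Object of class `model_choice`: `route` (one of
#'   `"compartmental_1"`, `"compartmental_2"`, `"nca_fallback"`),
#'   `reason_codes`, `fit` (the accepted or last attempted `fit_result`, may
#'   be `NULL`), `gof` (a `gof_score` when a fit exists).
#' @export
select_model <- function(profile, config = default_config()) {
  stopifnot(inherits(profile, "tdm_profile"))
  issues <- validate_profile(profile, config)
  if (any(issues$severity == "error"))
    stop("profile fails analysis preconditions: ",
         paste(unique(issues$code[issues$severity == "error"]),
               collapse = ", "), call. = FALSE)
  non_monotone <- any(issues$code == "non_monotone_decline")
  m <- n_active_samples(profile, post_infusion = TRUE)
  reasons <- character(0)

  strip <- tryCatch(strip_estimates(profile), error = function(e) NULL)
  if (is.null(strip)) {
    return(structure(list(route = "nca_fallback",
                          reason_codes = "no_converged_fit",
                          fit = NULL, gof = NULL),
                     class = "model_choice"))
  }
  fit1 <- tryCatch(fit_model(profile, 1L, strip, config),
                   error = function(e) NULL)
  chosen <- fit1
  if (m < config$min_points_2cpt) {
    reasons <- c(reasons, "few_points_1cpt_only")
  } else if (is.null(strip$candidate_2cpt)) {
    reasons <- c(reasons, "no_2cpt_candidate")
  } else {
    fit2 <- tryCatch(fit_model(profile, 2L, strip, config),
                     error = function(e) NULL)
    accept2 <- FALSE
    if (!is.null(fit2) && fit2$converged) {
      eig_ok <- fit2$macro$alpha / fit2$macro$beta >= config$eigenratio_min
      cv_ok <- all(is.finite(fit2$macro_cv)) &&
        all(fit2$macro_cv < config$cv_accept_2cpt)
      disc_ok <- if (!is.null(fit1)) {
        if (isTRUE(config$use_aicc)) .aicc(fit2) < .aicc(fit1)
        else .ftest_p(fit1, fit2) < config$ftest_alpha
      } else TRUE
      accept2 <- eig_ok && cv_ok && disc_ok
    }
    if (accept2) {
      chosen <- fit2
      reasons <- c(reasons, "accepted_2cpt")
    } else {
      reasons <- c(reasons, "rejected_2cpt")
    }
  }

  route <- if (!is.null(chosen)) paste0("compartmental_", chosen$model_order)
           else "nca_fallback"
  gof <- NULL
  if (is.null(chosen) || !chosen$converged) {
    route <- "nca_fallback"
    reasons <- c(reasons, "no_converged_fit")
  } else {
    # the three fallback conditions are an "or": evaluate all, report all
    gof <- gof_score(gof_components(chosen, profile), config)
    if (any(chosen$macro_cv >= config$cv_fallback)) {
      route <- "nca_fallback"
      reasons <- c(reasons, "high_param_cv")
    }
    if (non_monotone && gof$band == "red") {
      route <- "nca_fallback"
      reasons <- c(reasons, "non_monotone_red_fit")
    }
  }
  structure(list(route = route, reason_codes = reasons, fit = chosen,
                 gof = gof),
            class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat(sprintf("<model_choice> route=%s [%s]\n", x$route,
              paste(x$reason_codes, collapse = ", ")))
  if (!is.null(x$gof))
    cat(sprintf("  GOF %.1f/10 (%s)\n", x$gof$score, x$gof$band))
  invisible(x)
}

#' Override the automatic route choice
#'
#' Lets the user force the model-independent route, or force a compartmental
#' route after an automatic fallback. The reason code `user_override` is
#' appended so reports show the choice was manual.
#'
#' @param choice A `model_choice` from [select_model()].
#' @param user_route `"compartmental"` or `"nca"`.
#' @param profile The profile the choice was computed on (needed when the
#'   requested route must be (re)computed).
#' @param config An `analysis_config`.
#' @return An updated `model_choice`.
#' @export
override_route <- function(choice, user_route = c("compartmental", "nca"),
                           profile = NULL, config = default_config()) {
  stopifnot(inherits(choice, "model_choice"))
  user_route <- match.arg(user_route)
  if (user_route == "nca") {
    if (!is.null(profile) &&
        n_active_samples(profile, post_infusion = TRUE) < 3L)
      stop("non-compartmental route needs >= 3 post-infusion samples",
           call. = FALSE)
    choice$route <- "nca_fallback"
  } else {
    if (is.null(choice$fit) || !choice$fit$converged) {
      if (is.null(profile))
        stop("no converged compartmental fit available to override to",
             call. = FALSE)
      fit <- tryCatch(fit_model(profile, 1L, NULL, config),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged)
        stop("compartmental route not computable on this profile",
             call. = FALSE)
      choice$fit <- fit
      choice$gof <- gof_score(gof_components(fit, profile), config)
    }
    choice$route <- paste0("compartmental_", choice$fit$model_order)
  }
  choice$reason_codes <- c(choice$reason_codes, "user_override")
  choice
}
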