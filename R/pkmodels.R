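# Closed-form concentration-time solutions for zero-order IV infusion with
# first-order disposition (1- and 2-compartment), plus derived exposure
# quantities. Pure functions; all times in minutes, concentrations in mg/L.

#' One-compartment model parameters
#'
#' @param clearance_CL Clearance (L/min), > 0.
#' @param volume_V Volume of distribution (L), > 0.
#' @return Object of class `onecpt_params`; elimination rate
#'   \eqn{k = CL/V}.
#' @export
onecpt_params <- function(clearance_CL, volume_V) {
  if (!(is.finite(clearance_CL) && clearance_CL > 0))
    stop("clearance_CL must be > 0", call. = FALSE)
  if (!(is.finite(volume_V) && volume_V > 0))
    stop("volume_V must be > 0", call. = FALSE)
  structure(list(CL = clearance_CL, V = volume_V,
                 k = clearance_CL / volume_V),
            class = "onecpt_params")
}

#' Two-compartment model micro-constants
#'
#' Internal parameterization is micro-constant (central volume \eqn{V_1} and
#' rate constants \eqn{k_{10}, k_{12}, k_{21}}); macro constants (intercepts
#' and exponents) are derived via [macro_from_micro()].
#'
#' @param volume_V1 Central volume (L), > 0.
#' @param k10 Elimination rate constant from central (1/min), > 0.
#' @param k12,k21 Inter-compartmental rate constants (1/min), > 0.
#' @return Object of class `twocpt_params`; clearance \eqn{CL = V_1 k_{10}}.
#' @export
twocpt_params <- function(volume_V1, k10, k12, k21) {
  vals <- c(volume_V1, k10, k12, k21)
  if (!all(is.finite(vals) & vals > 0))
    stop("all two-compartment parameters must be finite and > 0",
         call. = FALSE)
  structure(list(V1 = volume_V1, k10 = k10, k12 = k12, k21 = k21,
                 CL = volume_V1 * k10),
            class = "twocpt_params")
}

#' Macro constants (intercepts and exponents) from micro-constants
#'
#' \eqn{\alpha} and \eqn{\beta} are the roots of
#' \eqn{s^2 - (k_{10}+k_{12}+k_{21}) s + k_{10} k_{21} = 0} with
#' \eqn{\alpha > \beta}; the bolus-normalized intercepts follow from the
#' standard partial-fraction expansion, so an IV bolus of dose \eqn{D} gives
#' \eqn{C(t) = D (A e^{-\alpha t} + B e^{-\beta t})}.
#'
#' @param params A [twocpt_params()].
#' @return List of class `macro_constants` with fields `A`, `B`
#'   (concentration per unit bolus dose, 1/L), `alpha`, `beta` (1/min).
#' @export
#' @examples
#' macro_from_micro(twocpt_params(20, 0.1, 0.05, 0.05))
macro_from_micro <- function(params) {
  stopifnot(inherits(params, "twocpt_params"))
  s <- params$k10 + params$k12 + params$k21
  p <- params$k10 * params$k21
  disc <- s^2 - 4 * p
  if (disc <= 0)
    stop("degenerate two-compartment model (repeated or complex exponents); ",
         "use the one-compartment model", call. = FALSE)
  rt <- sqrt(disc)
  alpha <- (s + rt) / 2
  beta  <- (s - rt) / 2
  A <- (alpha - params$k21) / (params$V1 * (alpha - beta))
  B <- (params$k21 - beta)  / (params$V1 * (alpha - beta))
  structure(list(A = A, B = B, alpha = alpha, beta = beta),
            class = "macro_constants")
}

#' Concentration-time function, one-compartment infusion model
#'
#' During the infusion (\eqn{t \le T_{inf}}):
#' \eqn{C(t) = (R_0/CL)(1 - e^{-kt})} with \eqn{R_0 = D/T_{inf}}; afterwards
#' the end-of-infusion concentration declines monoexponentially,
#' \eqn{C(t) = C(T_{inf}) e^{-k (t - T_{inf})}}.
#'
#' @param t Times (min since infusion start), vectorized.
#' @param params A [onecpt_params()].
#' @param dose An [infusion_event()].
#' @return Concentrations (mg/L).
#' @export
#' @examples
#' conc_onecpt(120, onecpt_params(0.25, 50), infusion_event(100, 120, 360))
conc_onecpt <- function(t, params, dose) {
  stopifnot(inherits(params, "onecpt_params"), inherits(dose, "infusion_event"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tinf <- dose$infusion_duration
  r0 <- dose$dose_amount / tinf
  k <- params$k
  plateau <- r0 / params$CL
  during <- pmin(t, tinf)
  c_during <- plateau * (1 - exp(-k * during))
  decay <- exp(-k * pmax(t - tinf, 0))
  c_during * decay
}

#' Concentration-time function, two-compartment infusion model
#'
#' Biexponential infusion solution built from the macro constants; each
#' exponential term accumulates as
#' \eqn{(R_0 c_\lambda / \lambda)(1 - e^{-\lambda t})} during the infusion
#' and decays from its end-of-infusion value afterwards. Continuous at
#' \eqn{t = T_{inf}} by construction.
#'
#' @inheritParams conc_onecpt
#' @param params A [twocpt_params()].
#' @return Concentrations (mg/L).
#' @export
conc_twocpt <- function(t, params, dose) {
  stopifnot(inherits(params, "twocpt_params"), inherits(dose, "infusion_event"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  mac <- macro_from_micro(params)
  tinf <- dose$infusion_duration
  r0 <- dose$dose_amount / tinf
  term <- function(coef, lambda) {
    during <- pmin(t, tinf)
    (r0 * coef / lambda) * (1 - exp(-lambda * during)) *
      exp(-lambda * pmax(t - tinf, 0))
  }
  term(mac$A, mac$alpha) + term(mac$B, mac$beta)
}

#' Model-predicted concentrations (generic over model order)
#'
#' @param t Times (min).
#' @param params `onecpt_params` or `twocpt_params`.
#' @param dose An [infusion_event()].
#' @return Concentrations (mg/L).
#' @export
conc_model <- function(t, params, dose) {
  if (inherits(params, "onecpt_params")) conc_onecpt(t, params, dose)
  else if (inherits(params, "twocpt_params")) conc_twocpt(t, params, dose)
  else stop("unknown parameter class", call. = FALSE)
}

#' Derived pharmacokinetic quantities
#'
#' Exposure identities under linear kinetics: \eqn{AUC_{0-\infty} = D/CL}
#' (single dose, equal to steady-state \eqn{AUC_\tau});
#' \eqn{C_{avg,ss} = AUC/\tau}; terminal half-life \eqn{\ln 2/k}
#' (one-compartment) or \eqn{\ln 2/\beta} (two-compartment);
#' \eqn{V_{ss} = V_1 (1 + k_{12}/k_{21})}.
#'
#' @param params `onecpt_params` or `twocpt_params`.
#' @param dose An [infusion_event()].
#' @return List of class `derived_pk`: `clearance_CL` (L/min), `Vss` (L),
#'   `terminal_half_life` (min), `AUC_0_inf` (mg·min/L), `Cavg_ss` (mg/L).
#' @export
derived_params <- function(params, dose) {
  stopifnot(inherits(dose, "infusion_event"))
  if (inherits(params, "onecpt_params")) {
    cl <- params$CL; vss <- params$V; lam <- params$k
  } else if (inherits(params, "twocpt_params")) {
    cl <- params$CL
    vss <- params$V1 * (1 + params$k12 / params$k21)
    lam <- macro_from_micro(params)$beta
  } else stop("unknown parameter class", call. = FALSE)
  auc <- dose$dose_amount / cl
  structure(list(clearance_CL = cl, Vss = vss,
                 terminal_half_life = log(2) / lam,
                 AUC_0_inf = auc,
                 Cavg_ss = auc / dose$dosing_interval_tau),
            class = "derived_pk")
}
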