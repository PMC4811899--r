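---
title: "Methods: compartmental curve fitting, fit-quality scoring and dose individualization for busulfan TDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental curve fitting, fit-quality scoring and dose individualization for busulfan TDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bustdm)
```

## The clinical problem

Busulfan conditioning before hematopoietic stem-cell transplantation has a
narrow therapeutic window: under-exposure risks graft failure and relapse,
over-exposure risks veno-occlusive disease. Pediatric centers therefore run
therapeutic drug monitoring (TDM) around one of the early doses — typically
0.8 mg/kg infused over 2 h every 6 h for 16 doses — draw several plasma
concentrations, estimate the patient's clearance, and adjust the remaining
doses to hit an exposure target expressed as AUC per dose, average
steady-state concentration (Cavg,ss), or cumulative course AUC.

`bustdm` implements the computational core of such a workflow: data intake
with point exclusion, compartmental curve fitting with automatic model
selection and a model-independent fallback, a 10-point fit-quality
"tachometer" for non-specialist users, exposure simulation and dose
recommendation, and report assembly with a duplicate-submission registry. A
seeded synthetic-cohort generator with an independent ODE oracle provides
the validation harness.

## Models

Both disposition models assume zero-order infusion input at rate
$R_0 = D/T_{inf}$ and linear (first-order) elimination.

**One compartment** ($CL$, $V$; $k = CL/V$):
$$
C(t) = \frac{R_0}{CL}\left(1 - e^{-kt}\right), \quad t \le T_{inf};
\qquad
C(t) = C(T_{inf})\, e^{-k (t - T_{inf})}, \quad t > T_{inf}.
$$

**Two compartments** (central volume $V_1$, micro-constants $k_{10}, k_{12},
k_{21}$): the exponents $\alpha > \beta > 0$ are the roots of
$s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0$ and the bolus-normalized
intercepts $A, B$ follow from the partial-fraction expansion. Each
exponential term accumulates during the infusion and decays from its
end-of-infusion value afterwards, which makes the solution continuous at
$T_{inf}$ by construction. The micro-constant parameterization is used
internally because it is the natural space for positivity constraints; the
macro constants (intercepts and exponents) are derived because the
fit-quality score consumes their CVs, and their uncertainties are obtained
by the first-order delta method. The mathematically possible repeated-root
case $\alpha = \beta$ cannot arise from strictly positive micro-constants
(the discriminant $(k_{10}-k_{21})^2 + k_{12}^2 + 2k_{12}(k_{10}+k_{21})$ is
strictly positive), so it is rejected defensively rather than handled with a
$t e^{-\alpha t}$ form.

Exposure identities under linear kinetics, used throughout the simulation
module: $AUC_{0-\infty} = D/CL$ for a single dose, which equals the
steady-state AUC over one dosing interval, and $C_{avg,ss} = AUC/\tau$.

Everything is validated against a brute-force oracle (`ode_oracle()`) that
integrates the mass-balance equations with `deSolve::lsoda` at relative
tolerance $10^{-10}$, splitting the integration at the end of infusion where
the input is discontinuous.

## Estimation

**Curve stripping** initializes the nonlinear fit. The last three
post-infusion points (the last half, rounded down, when more than six are
available — rounding down keeps the middle point with the fast phase, which
the worked tolerances of the stripping examples require) give the terminal
line $(B, \lambda)$ by log-linear regression; positive residuals of the
earlier points against that line, when at least two exist, give the fast
phase $(A, \alpha)$ by a second regression. Stripped post-infusion
intercepts are converted to bolus-equivalent intercepts with the factor
$\lambda T_{inf}/(1 - e^{-\lambda T_{inf}})$ before the standard
micro-constant algebra.

**Weighted nonlinear least squares.** The objective is
$\sum_i w_i (C_i - \hat C(t_i;\theta))^2$, minimized by the
Levenberg–Marquardt algorithm (`minpack.lm::nls.lm`) over log-transformed
parameters, which enforces positivity without box constraints. The default
weighting is predicted-value $w_i = 1/\max(\hat C_i, 0.01)^2$, refreshed
over three outer passes with frozen weights inside each pass, so the whole
fit is deterministic; $1/y^2$, $1/y$ and unweighted schemes are available in
the configuration. During-infusion samples, when present, enter the
objective with the same weighting. Convergence tolerances are a relative
parameter change below $10^{-8}$ or relative objective change below
$10^{-10}$, with a 200-iteration cap; hitting the cap is recorded as
non-convergence, not raised. Parameter CV% come from the scaled covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum on the log scale (where the
standard deviation of a log-parameter is its relative standard deviation)
and are propagated to the macro scale by the delta method. A rank-deficient
Jacobian sets the CVs to an `Inf` sentinel rather than failing.

**Nested model selection.** With fewer than 5 post-infusion points only the
one-compartment model is fit. Otherwise, when stripping yields a
biexponential candidate, both orders are fit and the two-compartment model
is accepted only if it converged, every macro CV is below 50%,
$\alpha/\beta \ge 2$, and the extra-sum-of-squares F-test rejects the nested
one-compartment model at $p < 0.05$ (AICc is available as an alternative
discriminator). The analysis falls back to the model-independent route when
no compartmental fit converged, when the accepted fit carries a CV at or
above 100%, or when the profile showed a non-monotone post-infusion decline
and the accepted fit's tachometer band is red. These three conditions are a
logical "or": all that hold are evaluated and reported, so a single profile
can carry several fallback reason codes. Every threshold lives in
`default_config()`; the published descriptions of such tools do not disclose
their exact cut-offs, so the values here are this package's explicit policy,
not a reproduction.

## The fit-quality tachometer

Each component metric — the weighted RMSE as a fraction of the weighted mean
observed concentration, and the CV% of each coefficient and exponent — is
log-adjusted against a reference and clamped:
$$
s_j = \mathrm{clamp}\left(10 - 3\log_{10}\frac{\max(m_j, 10^{-12})}{\mathrm{ref}_j},\ 0,\ 10\right),
$$
with references 0.10 for the RMSE fraction and 25% for CVs. A component at
its reference scores 10; ten times worse costs 3 points. The overall score
is the equal-weighted mean (weights configurable), displayed to one decimal
on a continuous 0–10 scale, and banded green ($\ge 7.0$), yellow
($[4.0, 7.0)$), red ($< 4.0$) with `>=` semantics exactly at the
boundaries. The references, slope, weights and cut-points are all
configuration, so a site can re-calibrate the tachometer without code
changes. Two consequences of this calibration are worth knowing: a perfect
fit scores exactly 10/green, and with three (one-compartment) or five
(two-compartment) equally weighted components a red band effectively
requires several components to be catastrophic at once — in practice red
co-occurs with CVs far beyond the 100% fallback threshold.

## Non-compartmental analysis

The terminal slope $\lambda_z$ is chosen by maximizing the adjusted $r^2$ of
log-linear regressions over candidate windows (the last $k$ positive
concentrations from the observed peak onward, $k \ge 3$), ties resolving to
the larger window; a non-negative best slope is a no-terminal-phase error.
AUC to the last sample uses the linear-up/log-down trapezoid with an
implicit (0 min, 0 mg/L) anchor at infusion start — the log trapezoid is
exact for a monoexponential through two points. Extrapolation uses the
regression-predicted (not observed) last concentration by default, which is
less noise-sensitive; the observed value is a configuration toggle.
$CL = D/AUC_{0-\infty}$. Quality flags mark extrapolated fractions above
20% and 3-point terminal fits with adjusted $r^2 < 0.95$.

Because the 0→first-sample segment is a linear chord under a concave rising
curve, NCA clearance agrees with the fitted clearance to well under 2% only
when the sampling grid is genuinely dense (including during-infusion
points); with the routine 5-sample schedule the chord bias is visible and
the compartmental route is preferred — one reason the tool treats NCA as a
fallback.

## Dose individualization

All three target kinds invert the linear-PK identities in closed form:
dose $= CL \cdot T$ for an AUC-per-dose target, $CL \cdot T \cdot \tau$ for
a Cavg,ss target, and
$CL\,(T - (n_c - 1) D_{cur}/CL)/(n_{tot} - n_c + 1)$ for a cumulative-AUC
target with a regimen change at dose $n_c$ of $n_{tot}$ (an already-met
target is a `target_already_exceeded` error). The cumulative-AUC target is
this package's extension beyond the per-dose AUC and Cavg,ss targets such
tools expose, and reports label it as such. `recommend_dose()` and
`exposure_for_dose()` are exact inverses, a property the tests exercise over
random regimens. Rounded what-if variants on a 5 mg grid (configurable) are
reported with their resulting exposures; recommendations are absolute mg,
with mg/kg shown informatively.

## The synthetic cohort generator

`default_population()` emulates a pediatric busulfan TDM study:
weights uniform on 10–60 kg; clearance lognormal with median 0.004 L/min/kg
and 25% CV; central volume lognormal with median 0.7 L/kg and 20% CV; 30%
of subjects carry a peripheral compartment with $k_{12}$ uniform on
0.005–0.03/min and $k_{21}$ on 0.01–0.04/min; 0.8 mg/kg infused over 120
min every 360 min, 16 doses; sampling at 135, 150, 180, 240 and 360 min
after infusion start; proportional noise 10% CV plus additive 0.01 mg/L.
These are literature-typical stand-ins chosen once — no published
distributional details exist for the validation cohorts of comparable
tools, and they are not presented as a reproduction of any. Noise is
truncated at zero by resampling (rather than flooring) to avoid a point
mass at zero concentration; flooring is a toggle. Optional sample
mistiming draws the blood at a perturbed true time while recording the
nominal time, emulating charting error.

The generator is fully deterministic: each profile's randomness flows from
a sub-seed derived from the master seed and the profile index, so cohorts
are reproducible and prefix-stable (`simulate_cohort(pop, k, seed)` is the
first *k* of `simulate_cohort(pop, n, seed)`).

`pathology_population()` adds a deliberate mixture of problem profiles —
sparse (4-point) records, contaminated mid-profile samples, rising terminal
phases, extreme (60% CV) noise, "garbage" profiles combining gross
contamination with extreme noise, and unusably sparse records — designed so
that a 1,000-profile cohort exercises every route (one-compartment,
two-compartment, NCA fallback) and every reason code of the selection
logic at least once, the desk-scale analog of exhaustive executable-path
testing. `recovery_study()` additionally exercises the manual override
branch once, since no automatic path can emit `user_override`.

What the generator does **not** emulate: assay-specific error structures,
covariate-driven (age- or maturation-dependent) clearance beyond per-kg
scaling, multi-dose accumulation (samples come from one interval of the
studied dose), and real charting artifacts beyond simple mistiming. Passing
tests on these cohorts therefore demonstrate correctness of the algorithms
under the stated error model, not performance on any site's real data.

## Numerical choices and problem sizes

- ODE oracle: `lsoda`, rtol $10^{-10}$, atol $10^{-14}$, integration split
  at $T_{inf}$. Closed-form agreement is asserted to $10^{-6}$ relative
  with a $10^{-6}$ mg/L floor; below that floor the integrator sits at its
  absolute-tolerance noise level, orders of magnitude below any assay LLOQ.
- Weight floor 0.01 mg/L in $1/\hat C^2$ weights guards near-zero
  predictions.
- Numerical derivatives (Jacobian, delta method) use central differences
  with relative step $10^{-6}$.
- Validation scales, chosen as desk-scale stand-ins for exhaustive
  simulation: 1,000-point oracle grids; 200 profiles per model order for
  exact recovery; 500-profile cohorts for selection consistency and noise
  calibration; 150-profile cohorts per noise level for tachometer
  monotonicity; 1,000-profile pathology cohorts for path coverage. The full
  study sizes are a flag away (`recovery_study(pop, n = 10000, ...)`).
- Ties: terminal-window selection in NCA breaks adjusted-$r^2$ ties (within
  $10^{-9}$) toward the larger window; even post-infusion counts split the
  stripping halves exactly.
- Degenerate inputs: profiles with fewer than 3 post-infusion points are
  not analyzable by any route; all-rising profiles fail stripping and NCA
  with classed errors that `recovery_study()` counts rather than raises.

## Worked example

```{r example}
profile <- tdm_profile("demo", 30, infusion_event(100, 120, 360, 5, 16),
                       data.frame(time = c(135, 150, 180, 240, 360),
                                  conc = c(1.898, 1.742, 1.468, 1.042, 0.525)))
choice <- select_model(profile)
choice
rec <- recommend_dose(choice$fit$params$CL,
                      therapeutic_target("cumulative_auc", 5600),
                      regimen(100, 360, total_doses = 16, change_at = 9,
                              studied_dose_number = 5),
                      dosing_weight = 30)
rec
```

## Known limitations

- Individual-profile least squares only: no Bayesian or population
  (NONMEM-style) estimation, no covariate models, no mid-course sparse-data
  forecasting.
- Single-dose fitting: the studied dose is analyzed in isolation, justified
  by linear-PK superposition for the exposure identities but not checked
  against accumulation in the data.
- No oral absorption, nonlinear elimination, or three-compartment models.
- The selection thresholds and tachometer calibration are explicit policy
  defaults, configurable per site; they have not been tuned against
  clinical outcome data.
- The EHR integration surface (push/pull, forms, screens) is out of scope;
  file I/O and the CLI stand in for it.
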