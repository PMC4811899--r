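test_that("stripping recovers a monoexponential tail exactly", {
  dose <- infusion_event(100, 120, 360)
  tp <- c(0, 60, 120, 240)
  p <- tdm_profile("s", 30, dose,
                   data.frame(time = 120 + tp, conc = 5 * exp(-0.01 * tp)))
  st <- strip_estimates(p)
  expect_equal(st$candidate_1cpt$B, 5, tolerance = 1e-10)
  expect_equal(st$candidate_1cpt$lambda, 0.01, tolerance = 1e-10)
  expect_null(st$candidate_2cpt)  # residuals all ~0, no second phase
  expect_equal(st$terminal_r2, 1, tolerance = 1e-9)
})

test_that("stripping resolves a biexponential within the expected tolerances", {
  dose <- infusion_event(100, 120, 480)
  tp <- c(0, 15, 30, 60, 120, 240, 360)
  cc <- 10 * exp(-0.05 * tp) + 2 * exp(-0.005 * tp)
  st <- strip_estimates(tdm_profile("s", 30, dose,
                                    data.frame(time = 120 + tp, conc = cc)))
  expect_equal(st$n_terminal, 3L)  # 7 points: last half, rounded down
  cand <- st$candidate_2cpt
  expect_false(is.null(cand))
  expect_equal(cand$beta, 0.005, tolerance = 0.02)
  expect_equal(cand$B, 2, tolerance = 0.05)
  expect_equal(cand$alpha, 0.05, tolerance = 0.15)
  expect_gt(cand$alpha, cand$beta)
})

test_that("stripping errors on non-declining or non-positive terminal data", {
  dose <- infusion_event(100, 120, 360)
  rising <- tdm_profile("s", 30, dose,
                        data.frame(time = c(135, 180, 240), conc = c(1, 2, 4)))
  expect_error(strip_estimates(rising), "not declining")
  few <- make_profile_1cpt(times = c(135, 180))
  expect_error(strip_estimates(few), ">= 3")
})

test_that("LM fit recovers exact one-compartment data to numerical precision", {
  p <- make_profile_1cpt(CL = 0.25, V = 50,
                         times = c(135, 150, 180, 240, 360))
  fit <- fit_model(p, 1L)
  expect_true(fit$converged)
  expect_equal(fit$params$CL, 0.25, tolerance = 1e-6)
  expect_equal(fit$params$V, 50, tolerance = 1e-6)
  expect_lt(fit$weighted_SS, 1e-16)
  expect_equal(fit$predictions, active_samples(p)$conc, tolerance = 1e-8)
  # repeated fits are bit-identical (no randomness in the LM path)
  expect_identical(fit_model(p, 1L)$params$CL, fit$params$CL)
  expect_identical(fit_model(p, 1L)$weighted_SS, fit$weighted_SS)
})

test_that("LM fit recovers exact two-compartment data and its macro CVs are finite", {
  p <- make_profile_2cpt()
  fit <- fit_model(p, 2L)
  expect_true(fit$converged)
  expect_equal(fit$params$V1, 20, tolerance = 1e-5)
  expect_equal(fit$params$CL, 20 * 0.006, tolerance = 1e-6)
  expect_true(all(is.finite(unlist(fit$macro_cv))))
  mac <- macro_from_micro(fit$params)
  expect_equal(fit$macro$alpha, mac$alpha)
})

test_that("accepted LM steps never increase the objective", {
  set.seed(403)
  pop <- default_population()
  for (i in 1:10) {
    sp <- simulate_profile(pop, 9000 + i)
    fit <- tryCatch(fit_model(sp$profile, 1L), error = function(e) NULL)
    if (is.null(fit)) next
    # within each reweighting pass the weights are fixed, so the accepted
    # LM steps must be non-increasing in the objective
    for (trace in fit$rss_trace)
      expect_true(all(diff(trace) <= 1e-12 * max(trace, 1e-300)))
  }
})

test_that("fitted CL lands within 15% of truth in >=90% of noisy replicates", {
  pop <- default_population(prop_noise_cv = 10, add_noise_sd = 0,
                            two_cpt_fraction = 0,
                            schedule = c(135, 150, 180, 240, 300, 360))
  hits <- logical(200)
  for (i in 1:200) {
    sp <- simulate_profile(pop, .derive_fixture_seed(604, i))
    fit <- tryCatch(fit_model(sp$profile, 1L), error = function(e) NULL)
    hits[i] <- !is.null(fit) && fit$converged &&
      abs(fit$params$CL - sp$truth$CL) / sp$truth$CL <= 0.15
  }
  expect_gte(mean(hits), 0.90)
})

test_that("nested selection follows the point-count and F-test rules", {
  # dense noise-free monoexponential: the F-test cannot favor 2-cpt
  p1 <- make_profile_1cpt(times = c(135, 150, 180, 240, 300, 360))
  ch1 <- select_model(p1)
  expect_equal(ch1$route, "compartmental_1")
  # dense noise-free biexponential with alpha/beta ~ 10
  p2 <- make_profile_2cpt(V1 = 20, k10 = 0.006, k12 = 0.02, k21 = 0.02)
  mac <- macro_from_micro(twocpt_params(20, 0.006, 0.02, 0.02))
  expect_gt(mac$alpha / mac$beta, 4)
  ch2 <- select_model(p2)
  expect_equal(ch2$route, "compartmental_2")
  expect_true("accepted_2cpt" %in% ch2$reason_codes)
  # m = 4: one-compartment only, two-compartment never attempted
  p3 <- make_profile_1cpt(times = c(135, 160, 200, 280))
  ch3 <- select_model(p3)
  expect_equal(ch3$route, "compartmental_1")
  expect_true("few_points_1cpt_only" %in% ch3$reason_codes)
  # m < 3 is not analyzable at all
  p4 <- make_profile_1cpt(times = c(135, 240))
  expect_error(select_model(p4), "preconditions")
})

test_that("user override switches the route and is recorded", {
  p <- make_profile_1cpt(times = c(135, 150, 180, 240, 360))
  ch <- select_model(p)
  ov <- override_route(ch, "nca", p)
  expect_equal(ov$route, "nca_fallback")
  expect_true("user_override" %in% ov$reason_codes)
  # overriding back to compartmental restores the fitted route
  back <- override_route(ov, "compartmental", p)
  expect_equal(back$route, "compartmental_1")
  expect_identical(back$fit$params$CL, ch$fit$params$CL)
  # override to a route that cannot be computed errors
  empty <- structure(list(route = "nca_fallback", reason_codes = "x",
                          fit = NULL, gof = NULL), class = "model_choice")
  expect_error(override_route(empty, "compartmental"), "no converged")
  sparse <- make_profile_1cpt(times = c(30, 135, 240))  # 2 post-infusion
  expect_error(override_route(ch, "nca", sparse), ">= 3")
})

test_that("fit is invariant to the stored ordering of samples", {
  p <- make_profile_1cpt(times = c(135, 150, 180, 240, 360))
  shuffled <- p$samples[c(3, 1, 5, 2, 4), ]
  q <- tdm_profile(p$patient_id, p$dosing_weight, p$dose, shuffled)
  expect_identical(fit_model(q, 1L)$params$CL, fit_model(p, 1L)$params$CL)
})
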