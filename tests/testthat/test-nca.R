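test_that("lambda_z matches exact geometric halving", {
  p <- tdm_profile("x", 30, infusion_event(100, 120, 360),
                   data.frame(time = c(120, 180, 240), conc = c(8, 4, 2)))
  lz <- lambda_z(p)
  expect_equal(lz$lambda_z, log(2) / 60, tolerance = 1e-12)
  expect_equal(lz$r2_adj, 1, tolerance = 1e-12)
  expect_equal(lz$n_terminal, 3L)
})

test_that("window selection prefers the largest window among r2 ties", {
  tp <- c(120, 180, 240, 300, 360, 420)
  p <- tdm_profile("x", 30, infusion_event(100, 120, 480),
                   data.frame(time = tp, conc = 6 * exp(-0.008 * (tp - 120))))
  expect_equal(lambda_z(p)$n_terminal, 6L)
})

test_that("a rising terminal phase is a no-terminal-phase error", {
  p <- tdm_profile("x", 30, infusion_event(100, 120, 360),
                   data.frame(time = c(135, 180, 240, 300),
                              conc = c(1, 1.2, 1.5, 2)))
  expect_error(lambda_z(p), "no declining terminal phase")
  expect_error(nca_analyze(p), "no declining terminal phase")
  # a late peak leaves too few declining points to call a terminal phase
  p2 <- tdm_profile("x", 30, infusion_event(100, 120, 360),
                    data.frame(time = c(135, 180, 240, 300),
                               conc = c(1, 1.5, 3, 2)))
  expect_error(lambda_z(p2), "no declining terminal phase")
})

test_that("trapezoid uses linear-up and log-down pieces with the (0,0) anchor", {
  p <- tdm_profile("x", 30, infusion_event(100, 120, 360),
                   data.frame(time = c(120, 240), conc = c(8, 2)))
  # ascending anchor piece: triangle 0.5*120*8; descending log piece
  expect_equal(auc_trapezoid(p), 480 + 120 * 6 / log(4), tolerance = 1e-12)
  expect_equal(120 * 6 / log(4), 519.4, tolerance = 1e-4)
  # linearity: doubling every concentration doubles the AUC
  p2 <- tdm_profile("x", 30, p$dose,
                    data.frame(time = c(120, 240), conc = c(16, 4)))
  expect_equal(auc_trapezoid(p2), 2 * auc_trapezoid(p), tolerance = 1e-12)
})

test_that("AUC is invariant to collinear point insertion", {
  dose <- infusion_event(100, 120, 360)
  # linear piece: midpoint of the ascending anchor chord
  p <- tdm_profile("x", 30, dose, data.frame(time = c(120, 240), conc = c(8, 2)))
  p_lin <- tdm_profile("x", 30, dose,
                       data.frame(time = c(60, 120, 240), conc = c(4, 8, 2)))
  expect_lt(abs(auc_trapezoid(p_lin) - auc_trapezoid(p)), 1e-9)
  # log piece: point on the exponential through (120,8),(240,2)
  k <- log(4) / 120
  p_log <- tdm_profile("x", 30, dose,
                       data.frame(time = c(120, 180, 240),
                                  conc = c(8, 8 * exp(-k * 60), 2)))
  expect_lt(abs(auc_trapezoid(p_log) - auc_trapezoid(p)), 1e-6)
})

test_that("extrapolated AUC approaches the analytic integral on a long tail", {
  # near-bolus input, samples spanning 3 half-lives
  lam <- log(2) / 100
  dose <- infusion_event(100, 1, 2000)
  tp <- 1 + c(0, 50, 100, 150, 200, 250, 300)
  p <- tdm_profile("x", 30, dose,
                   data.frame(time = tp, conc = 4 * exp(-lam * (tp - 1))))
  res <- nca_analyze(p)
  analytic <- 4 / lam + 0.5 * 1 * 4  # tail + linear rise over the 1-min infusion
  expect_equal(res$auc_inf, analytic, tolerance = 5e-3)
  expect_equal(res$lambda_z, lam, tolerance = 1e-10)
})

test_that("quality flags fire at their thresholds", {
  # coarse late sampling leaves > 20% of the AUC extrapolated
  pop <- default_population(prop_noise_cv = 0, add_noise_sd = 0,
                            two_cpt_fraction = 0,
                            schedule = c(135, 150, 180, 240))
  sp <- simulate_profile(pop, 31)
  res <- nca_analyze(sp$profile)
  expect_gt(res$extrap_fraction, 0.20)
  expect_true("high_extrapolation" %in% res$flags)
  expect_equal(res$extrap_fraction,
               (res$auc_inf - res$auc_last) / res$auc_inf)
  expect_equal(res$clearance_CL, sp$profile$dose$dose_amount / res$auc_inf)
})

test_that("NCA clearance scales linearly with dose at fixed concentrations", {
  p <- make_profile_1cpt(times = c(135, 150, 180, 240, 300, 360))
  res1 <- nca_analyze(p)
  p2 <- p
  p2$dose$dose_amount <- 2 * p$dose$dose_amount
  res2 <- nca_analyze(p2)
  expect_equal(res2$clearance_CL, 2 * res1$clearance_CL, tolerance = 1e-12)
  expect_identical(res2$auc_inf, res1$auc_inf)
})
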