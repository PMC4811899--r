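test_that("simulation is deterministic and honors degenerate settings", {
  pop <- default_population()
  a <- simulate_profile(pop, 123)
  b <- simulate_profile(pop, 123)
  expect_identical(a, b)
  # zero noise: observed concentrations equal the model exactly
  pop0 <- default_population(prop_noise_cv = 0, add_noise_sd = 0)
  sp <- simulate_profile(pop0, 9)
  expect_equal(sp$profile$samples$conc,
               conc_model(sp$profile$samples$time, sp$truth$params,
                          sp$profile$dose),
               tolerance = 1e-14)
  # forced model order
  pop2 <- default_population(two_cpt_fraction = 1)
  orders <- vapply(1:20, function(i) simulate_profile(pop2, i)$truth$model_order,
                   integer(1))
  expect_true(all(orders == 2L))
})

test_that("cohorts are seed-stable and prefix-stable", {
  pop <- default_population()
  c10 <- simulate_cohort(pop, 10, 42)
  c5 <- simulate_cohort(pop, 5, 42)
  expect_identical(c10[1:5], unclass(c5)[1:5])
  expect_identical(simulate_cohort(pop, 10, 42), c10)
})

test_that("population medians are recovered at cohort scale", {
  pop <- default_population()
  cohort <- simulate_cohort(pop, 1000, 7)
  cl_per_kg <- vapply(cohort, function(sp) sp$truth$CL / sp$truth$weight,
                      numeric(1))
  expect_equal(median(cl_per_kg), pop$cl_per_kg_median, tolerance = 0.05)
  v_per_kg <- vapply(cohort, function(sp) {
    v <- if (sp$truth$model_order == 1L) sp$truth$params$V
         else sp$truth$params$V1
    v / sp$truth$weight
  }, numeric(1))
  expect_equal(median(v_per_kg), pop$v_per_kg_median, tolerance = 0.05)
})

test_that("the proportional noise model is honest about its own magnitude", {
  pop <- default_population(prop_noise_cv = 10, add_noise_sd = 0)
  logres <- unlist(lapply(1:250, function(i) {
    sp <- simulate_profile(pop, .derive_fixture_seed(77, i))
    true <- conc_model(sp$profile$samples$time, sp$truth$params,
                       sp$profile$dose)
    log(sp$profile$samples$conc / true)
  }))
  expect_gt(length(logres), 1000)
  expect_equal(sd(logres), 0.10, tolerance = 0.10)
})

test_that("the ODE oracle reproduces both closed forms on a random grid", {
  set.seed(407)
  rel_err <- function(a, b) max(abs(a - b) / pmax(b, 1e-6))
  for (i in 1:10) {
    dose <- infusion_event(runif(1, 20, 200), runif(1, 30, 180), 1500)
    tt <- sort(c(runif(5, 0.5, dose$infusion_duration),
                 runif(10, dose$infusion_duration, 1440)))
    p1 <- onecpt_params(runif(1, 0.05, 0.4), runif(1, 10, 60))
    expect_lt(rel_err(ode_oracle(p1, dose, tt), conc_onecpt(tt, p1, dose)),
              1e-6)
    p2 <- twocpt_params(runif(1, 5, 50), runif(1, 0.002, 0.02),
                        runif(1, 0.005, 0.05), runif(1, 0.005, 0.05))
    expect_lt(rel_err(ode_oracle(p2, dose, tt), conc_twocpt(tt, p2, dose)),
              1e-6)
  }
  # zero-dose input decays nothing into the system
  z <- ode_oracle(onecpt_params(0.2, 30),
                  list(dose_amount = 0, infusion_duration = 60),
                  c(10, 60, 120))
  expect_equal(z, c(0, 0, 0))
})

test_that("noise-free recovery is exact through the full pipeline", {
  rep0 <- recovery_study(default_population(prop_noise_cv = 0,
                                            add_noise_sd = 0), 200, 3)
  expect_lt(abs(rep0$cl_bias_median_pct), 0.1)
  expect_lt(rep0$cl_rmse_pct, 0.1)
  expect_equal(sum(rep0$route_counts), 200)
})

test_that("the pathology mix reaches the fallback route", {
  rep <- recovery_study(pathology_population(), 150, 13)
  expect_gte(rep$route_counts[["nca_fallback"]], 1)
  expect_true("no_converged_fit" %in% names(rep$reason_counts))
})

test_that("a cohort can be written out and read back", {
  pop <- default_population()
  cohort <- simulate_cohort(pop, 3, 55)
  dir <- tempfile("cohort")
  write_cohort(cohort, dir, "csv")
  expect_true(file.exists(file.path(dir, "truth.json")))
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  expect_length(files, 3L)
  back <- read_profile(files[1])
  ids <- vapply(cohort, function(sp) sp$profile$patient_id, character(1))
  orig <- cohort[[match(back$patient_id, ids)]]$profile
  expect_equal(back$samples$conc, orig$samples$conc, tolerance = 1e-12)
})
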