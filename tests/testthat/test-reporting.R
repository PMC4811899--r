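# A complete analysis bundled into a report, built once for the whole file.
mk_run <- function(route = c("compartmental", "nca")) {
  route <- match.arg(route)
  p <- make_profile_1cpt(times = c(135, 150, 180, 240, 360),
                         patient_id = "pt-42", dose_number = 5L)
  ch <- select_model(p)
  nca <- NULL
  if (route == "nca") {
    ch <- override_route(ch, "nca", p)
    nca <- nca_analyze(p)
  }
  CL <- if (route == "nca") nca$clearance_CL else ch$fit$params$CL
  rec <- recommend_dose(CL, therapeutic_target("cumulative_auc", 5600),
                        regimen(100, 360, 16, 9, studied_dose_number = 5),
                        dosing_weight = p$dosing_weight)
  list(profile = p, choice = ch, rec = rec, nca = nca)
}

test_that("reports carry exactly one of fit or NCA result per route", {
  run <- mk_run("compartmental")
  rep <- build_report(run$profile, run$choice, run$rec,
                      created_at = "2026-09-25 08:00:00")
  expect_false(is.null(rep$fit))
  expect_null(rep$nca)
  run2 <- mk_run("nca")
  rep2 <- build_report(run2$profile, run2$choice, run2$rec, nca = run2$nca,
                       created_at = "2026-09-25 08:00:00")
  expect_null(rep2$fit)
  expect_false(is.null(rep2$nca))
  # an NCA route without the NCA result is a consistency error
  expect_error(build_report(run2$profile, run2$choice, run2$rec,
                            created_at = "now"), "requires an nca_result")
  expect_error(build_report(run$profile, run$choice, run$rec), "created_at")
})

test_that("report JSON round-trips losslessly", {
  run <- mk_run("compartmental")
  rep <- build_report(run$profile, run$choice, run$rec, comments = "ok to push",
                      created_at = "2026-09-25 08:00:00")
  path <- tempfile(fileext = ".json")
  report_to_json(rep, path)
  back <- report_from_json(path)
  expect_equal(back$recommendation$recommended_dose,
               rep$recommendation$recommended_dose, tolerance = 1e-15)
  expect_equal(back$fit$params$CL, rep$fit$params$CL, tolerance = 1e-15)
  expect_equal(back$samples, rep$samples, tolerance = 1e-15)
  expect_identical(back$comments, rep$comments)
  expect_identical(back$created_at, rep$created_at)
  # re-serialization is byte-identical: nothing was lost or reordered
  expect_identical(as.character(report_to_json(back)),
                   as.character(report_to_json(rep)))
})

test_that("report generation is deterministic under an injected clock", {
  r1 <- local({ run <- mk_run("compartmental")
    build_report(run$profile, run$choice, run$rec,
                 created_at = "2026-01-01 00:00:00") })
  r2 <- local({ run <- mk_run("compartmental")
    build_report(run$profile, run$choice, run$rec,
                 created_at = "2026-01-01 00:00:00") })
  expect_identical(as.character(report_to_json(r1)),
                   as.character(report_to_json(r2)))
})

test_that("report JSON schema is stable", {
  run <- mk_run("compartmental")
  rep <- build_report(run$profile, run$choice, run$rec,
                      created_at = "2026-09-25 08:00:00")
  parsed <- jsonlite::fromJSON(report_to_json(rep))
  expect_setequal(names(parsed),
                  c("patient_id", "study", "created_at", "route",
                    "reason_codes", "samples", "n_excluded", "fit", "nca",
                    "gof", "recommendation", "comments", "software_version",
                    "config_digest"))
  expect_setequal(names(parsed$recommendation),
                  c("current_dose", "recommended_dose",
                    "change_at_dose_number", "total_doses", "clearance_CL",
                    "target", "predicted", "rounded_variants"))
  expect_match(parsed$config_digest, "^[0-9a-f]{32}$")
})

test_that("the registry warns on duplicate patient+study, never blocks", {
  run <- mk_run("compartmental")
  rep <- build_report(run$profile, run$choice, run$rec,
                      created_at = "2026-09-25 08:00:00")
  reg <- report_registry(tempfile(fileext = ".jsonl"))
  r1 <- register_report(reg, rep)
  expect_true(r1$stored)
  expect_false(r1$duplicate_warning)
  r2 <- register_report(reg, rep)
  expect_true(r2$stored)
  expect_true(r2$duplicate_warning)
  # same child, different study: no warning under the default key
  rep_b <- rep
  rep_b$study$dose_number <- 9L
  r3 <- register_report(reg, rep_b)
  expect_false(r3$duplicate_warning)
  # ... but the strict child-only mode does warn
  cfg <- default_config()
  cfg$registry_key <- "patient_only"
  r4 <- register_report(reg, rep_b, cfg)
  expect_true(r4$duplicate_warning)
  # append-only audit: count equals the number of successful registrations
  expect_equal(registry_count(reg), 4L)
})

test_that("config digest is deterministic and sensitive to values", {
  expect_identical(config_digest(), config_digest())
  cfg <- default_config()
  cfg$ftest_alpha <- 0.01
  expect_false(identical(config_digest(cfg), config_digest()))
})

test_that("the text rendering walks the four-screen flow", {
  run <- mk_run("compartmental")
  rep <- build_report(run$profile, run$choice, run$rec, comments = "reviewed",
                      created_at = "2026-09-25 08:00:00")
  txt <- format(rep)
  expect_true(any(grepl("Patient data", txt)))
  expect_true(any(grepl("Model fit", txt)))
  expect_true(any(grepl("recommendation", txt)))
  expect_true(any(grepl("reviewed", txt)))
})
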