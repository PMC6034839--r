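test_that("simulation is deterministic for a fixed seed", {
  cfg <- simulation_config(n_patients = 40, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_cohort(simulation_config(n_patients = 40, seed = 43))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("noiseless measurements identify the true TVDT exactly", {
  coh <- simulate_cohort(simulation_config(n_patients = 60, noise_sd = 0,
                                           seed = 7))
  for (p in coh) {
    r <- recover_parameters(p)
    expect_true(r$ok)
    expect_equal(r$tvdt_days, p$true_tvdt, tolerance = 1e-9)
    expect_equal(r$timeline$survival_years, p$true_timeline$survival_years,
                 tolerance = 1e-9)
  }
  sm <- summarize_recovery(coh)
  expect_equal(sm$n_excluded, 0)
  expect_equal(sm$median_rel_tvdt_error, 0, tolerance = 1e-9)
  expect_equal(sm$mean_survival_bias_years, 0, tolerance = 1e-9)
})

test_that("recovery error grows with measurement noise and stays bounded", {
  errs <- vapply(c(0.01, 0.03, 0.05), function(ns) {
    coh <- simulate_cohort(simulation_config(n_patients = 500, noise_sd = ns,
                                             gap_days = 90, seed = 123))
    summarize_recovery(coh)$median_rel_tvdt_error
  }, 0)
  expect_true(all(diff(errs) > 0))   # monotone in noise s.d.
  expect_lt(errs[3], 0.25)           # 5% noise, 90 d gap: median error < 25%
})

test_that("non-growing noisy pairs are flagged and excluded, not fatal", {
  p <- structure(list(
    id = 1L, stage = "T1c", true_tvdt = 70, true_diameter_at_surgery = 15,
    measurements = data.frame(offset_days = c(0, 90),
                              true_diameter_mm = c(14, 15),
                              observed_diameter_mm = c(15.2, 15.0)),
    true_timeline = compute_timeline(15, list(tvdt_days = 70))
  ), class = "compas_patient")
  r <- recover_parameters(p)
  expect_false(r$ok)
  expect_match(r$reason, "non-growth")

  coh <- structure(list(p), class = "compas_cohort",
                   config = simulation_config(n_patients = 1))
  sm <- summarize_recovery(coh)
  expect_equal(sm$n_excluded, 1)

  one <- p
  one$measurements <- one$measurements[1, ]
  expect_error(recover_parameters(one), "two measurements")
})

test_that("cohorts round-trip through CSV and JSON", {
  coh <- simulate_cohort(simulation_config(n_patients = 8, seed = 3))
  df <- as.data.frame(coh)
  expect_equal(nrow(df), 16)  # two measurements per patient

  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  on.exit(unlink(c(csv, json)), add = TRUE)
  write_cohort(coh, csv, "csv")
  write_cohort(coh, json, "json")
  back_csv <- read_cohort(csv)
  back_json <- read_cohort(json)
  expect_equal(back_csv$observed_diameter_mm, df$observed_diameter_mm,
               tolerance = 1e-12)
  expect_equal(back_json$observed_diameter_mm, df$observed_diameter_mm,
               tolerance = 1e-12)
  expect_equal(back_json$patient_id, df$patient_id)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(n_patients = 0), ">= 1")
  expect_error(simulation_config(noise_sd = -1), ">= 0")
  expect_error(simulation_config(gap_days = 0), "> 0")
  expect_error(simulate_cohort(simulation_config(stages = "T4")),
               "size-determined")
  expect_error(simulate_cohort(simulation_config(stages = "T3",
                                                 max_diameter = 40)),
               "degenerate")
})

test_that("recovered timelines converge to truth as noise shrinks", {
  bias <- vapply(c(0.05, 0.01, 0.002), function(ns) {
    coh <- simulate_cohort(simulation_config(n_patients = 200, noise_sd = ns,
                                             seed = 99))
    abs(summarize_recovery(coh)$mean_survival_bias_years)
  }, 0)
  expect_true(bias[3] < bias[1])
  expect_lt(bias[3], 0.05)
})
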