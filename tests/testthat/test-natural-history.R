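test_that("timeline reproduces the published per-stage values", {
  # T1a column
  t1a <- compute_timeline(4.5, stage_parameters("T1a"))
  expect_equal(t1a$mts_doublings_at_surgery, 6.44, tolerance = 0.005 / 6.44)
  expect_equal(round(t1a$mts_diameter_at_surgery, 2), 0.04)
  expect_equal(round_half_up(t1a$wnh_years, 1), 11.5)
  expect_equal(round_half_up(t1a$survival_years, 1), 6.4)
  # T3 column
  t3 <- compute_timeline(64.6, stage_parameters("T3"))
  expect_equal(round_half_up(t3$survival_years, 1), 3.6)
  expect_equal(round_half_up(t3$visible_mts_years, 1), 1.7)
  expect_equal(round_half_up(t3$total_pt_years, 1), 6.2)
  # T2 column
  t2 <- compute_timeline(28.5, stage_parameters("T2"))
  expect_equal(round_half_up(t2$nonvisible_mts2_years, 1), 2.7)
  expect_equal(round_half_up(t2$visible_mts_years, 1), 1.9)
})

test_that("stage-inferring wrapper matches the explicit pipeline", {
  tl <- timeline_for_diameter(15.1)
  expect_equal(tl$stage, "T1c")
  expect_equal(tl$tvdt_days, 70)
  expect_equal(round_half_up(tl$survival_years, 1), 5.4)
  ref <- compute_timeline(15.1, stage_parameters(classify_t_stage(15.1)))
  expect_equal(unclass(tl), unclass(ref))
  expect_equal(round_half_up(timeline_for_diameter(8.5)$nonvisible_mts2_years,
                             1), 3.9)
  expect_error(timeline_for_diameter(0.5), "unstageable")
})

test_that("seeding boundary and degenerate inputs are flagged, not fatal", {
  # at the seeding size (20 doublings, ~1.016 mm) the visible-PT period
  # vanishes and seeding is instantaneous
  d_seed <- diameter_from_doublings(20)
  tl <- compute_timeline(d_seed, list(tvdt_days = 70))
  expect_equal(tl$visible_pt_years, 0)
  expect_equal(tl$mts_doublings_at_surgery, 0, tolerance = 1e-9)
  expect_true(tl$mts_seeded)

  sub <- compute_timeline(0.5, list(tvdt_days = 70))
  expect_false(sub$mts_seeded)
  expect_equal(sub$mts_diameter_at_surgery, 0)
  expect_equal(sub$nonvisible_mts1_years, 0)

  expect_error(compute_timeline(20000, list(tvdt_days = 70)), "lethal")
  expect_error(compute_timeline(0.005, list(tvdt_days = 70)), "founder")
  expect_error(compute_timeline(10, list(tvdt_days = -1)), "positive")

  # surgery after the MTS is already clinically manifest: clamped to zero
  big <- compute_timeline(1000, list(tvdt_days = 70))
  expect_true(big$mts_manifest_at_surgery)
  expect_equal(big$nonvisible_mts2_years, 0)
})

test_that("period-sum conservation and monotonicity hold over 1-75 mm", {
  c0 <- model_constants()
  # sweep the staged size range; start just past the seeding size (the
  # four-period decomposition exists only once the MTS has been seeded)
  ds <- seq(1.02, 75, length.out = 200)
  prev_surv <- Inf
  prev_mtsd <- -Inf
  for (d in ds) {
    tl <- compute_timeline(d, list(tvdt_days = 70), c0)
    expect_equal(tl$nonvisible_pt_years + tl$visible_pt_years +
                   tl$nonvisible_mts2_years + tl$visible_mts_years,
                 tl$wnh_years, tolerance = 1e-9)
    expect_equal(tl$survival_years,
                 tl$nonvisible_mts2_years + tl$visible_mts_years,
                 tolerance = 1e-9)
    expect_equal(tl$nonvisible_mts1_years, tl$visible_pt_years,
                 tolerance = 1e-12)
    expect_true(tl$survival_years < prev_surv)
    expect_true(tl$mts_diameter_at_surgery > prev_mtsd)
    prev_surv <- tl$survival_years
    prev_mtsd <- tl$mts_diameter_at_surgery
  }
})

test_that("survival vanishes as the PT approaches the lethal clock", {
  c0 <- model_constants()
  d_lethal <- diameter_from_doublings(60, c0)
  tl <- compute_timeline(d_lethal * (1 - 1e-12), list(tvdt_days = 70), c0)
  expect_equal(tl$survival_years, 0, tolerance = 1e-6)
})

test_that("calendar anchoring orders events and places the lethal date", {
  tl <- timeline_for_diameter(4.5)
  ev <- anchor_events(tl, as.Date("2000-01-01"))
  expect_named(ev, c("first_pt_cell", "pt_visible", "mts_seeded", "surgery",
                     "mts_visible", "lethal"))
  expect_equal(unname(unclass(ev[["surgery"]])),
               unclass(as.Date("2000-01-01")))
  # oracle: survival days from the closed form (60 - 3 log2(450)) * 70
  surv_days <- (60 - 3 * log2(4.5 / 0.01)) * 70
  expect_equal(as.numeric(ev[["lethal"]] - ev[["surgery"]]),
               round(surv_days))
  # strict ordering for every per-stage mean diameter
  for (d in default_diameters) {
    evd <- anchor_events(timeline_for_diameter(d), as.Date("2010-06-15"))
    expect_true(all(diff(unclass(evd)) > 0))
  }
  # seeding coincides with surgery when the PT is exactly at seeding size
  ev1 <- anchor_events(compute_timeline(1, list(tvdt_days = 70)),
                       as.Date("2000-01-01"))
  expect_equal(ev1[["mts_seeded"]], ev1[["surgery"]])
})

test_that("growth curves are consistent with the timeline", {
  c0 <- model_constants()
  tl <- compute_timeline(28.5, stage_parameters("T2"), c0)
  cur <- growth_curve(28.5, stage_parameters("T2"), c0, step_days = 10)

  # PT hits the 1 mm visibility threshold at the end of the non-visible period
  t_vis <- tl$nonvisible_pt_years * c0$days_per_year
  i <- which.min(abs(cur$t_days - t_vis))
  expect_equal(cur$pt_diameter_mm[i], 1.0, tolerance = 0.05)

  # at the surgery offset the MTS diameter matches the timeline
  t_surg <- tl$total_pt_years * c0$days_per_year
  j <- which(abs(cur$t_days - t_surg) < 1e-6)
  expect_length(j, 1L)
  expect_equal(cur$mts_diameter_mm[j], tl$mts_diameter_at_surgery,
               tolerance = 1e-9)
  expect_true(all(is.na(cur$pt_diameter_mm[cur$t_days > t_surg])))
  expect_true(all(cur$mts_diameter_mm[cur$t_days < t_vis] == 0))

  # final sample sits at the lethal endpoint, ~103 mm
  expect_equal(round(cur$mts_diameter_mm[nrow(cur)]), 103)
  expect_error(growth_curve(28.5, stage_parameters("T2"), c0, step_days = 0),
               "positive")
})

test_that("timelines serialize to data.frame and JSON", {
  tl <- timeline_for_diameter(15.1)
  df <- as.data.frame(tl)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("wnh_years", "survival_years", "nonvisible_mts2_years")
                  %in% names(df)))
  js <- jsonlite::fromJSON(jsonlite::toJSON(unclass(tl), auto_unbox = TRUE,
                                            digits = NA))
  expect_equal(js$survival_years, tl$survival_years, tolerance = 1e-6)
})
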