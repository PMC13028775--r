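test_that("intensity classification follows the dose ranges with closed bounds", {
  expect_identical(as.character(classify_intensity("atorvastatin", 40)),
                   "high")
  expect_identical(as.character(classify_intensity("rosuvastatin", 5)),
                   "moderate")
  expect_identical(as.character(classify_intensity("simvastatin", 10)),
                   "low")
  expect_identical(as.character(classify_intensity("atorvastatin", 5)),
                   "unclassifiable")
  # between listed ranges: not covered by any closed interval
  expect_identical(as.character(classify_intensity("atorvastatin", 30)),
                   "unclassifiable")
  # bounds are inclusive at both ends
  expect_identical(as.character(classify_intensity("atorvastatin", c(10, 20, 80))),
                   c("moderate", "moderate", "high"))
  expect_error(classify_intensity("lovastatin", 20), "lovastatin")
  expect_error(classify_intensity("atorvastatin", 0), "positive")
})

test_that("course derivation classifies the first intensity transition", {
  # moderate -> high at day 90: escalation
  ev <- make_events(c(0, 90), "atorvastatin", c(20, 40))
  cr <- derive_course(ev)
  expect_identical(as.character(cr$modification), "escalation")
  expect_identical(cr$time_to_first_change, 90)
  expect_true(cr$event)

  # constant regimen: censored at follow-up
  ev <- make_events(c(0, 30, 60), "atorvastatin", 20)
  cr <- derive_course(ev)
  expect_identical(as.character(cr$modification), "no_change")
  expect_identical(cr$time_to_first_change, 365)
  expect_false(cr$event)
  expect_identical(cr$switch_count, 0L)

  # same-intensity drug switch: class preserved, switch counted
  ev <- make_events(c(0, 60), c("atorvastatin", "rosuvastatin"), c(20, 10))
  cr <- derive_course(ev)
  expect_identical(as.character(cr$modification), "no_change")
  expect_identical(cr$switch_count, 1L)

  # first transition defines class even if later reversed
  ev <- make_events(c(0, 90, 180), "atorvastatin", c(20, 40, 20))
  cr <- derive_course(ev)
  expect_identical(as.character(cr$modification), "escalation")
  expect_identical(cr$time_to_first_change, 90)

  # unclassifiable doses are skipped for transitions but count as switches
  ev <- make_events(c(0, 60, 120), "atorvastatin", c(20, 30, 20))
  cr <- derive_course(ev)
  expect_identical(as.character(cr$modification), "no_change")
  expect_identical(cr$switch_count, 2L)

  expect_error(derive_course(make_events(numeric(0), character(0),
                                         numeric(0))), "no dispensing")
  expect_message(
    cr <- derive_course(make_events(c(0, 400), "atorvastatin", c(20, 40))),
    "beyond follow-up")
  expect_identical(as.character(cr$modification), "no_change")
})

test_that("reversing a two-step escalation yields de-escalation", {
  up <- make_events(c(0, 100), "rosuvastatin", c(10, 20))
  down <- make_events(c(0, 100), "rosuvastatin", c(20, 10))
  expect_identical(as.character(derive_course(up)$modification),
                   "escalation")
  expect_identical(as.character(derive_course(down)$modification),
                   "de_escalation")
})

test_that("course derivation matches a brute-force scan on random trajectories", {
  # independent oracle: explicit scan over consecutive classified pairs
  brute <- function(ev, followup = 365) {
    ev <- ev[ev$date <= followup, ]
    ev <- ev[order(ev$date), ]
    lv <- as.character(classify_intensity(ev$drug, ev$dose_mg))
    ord <- c(low = 1, moderate = 2, high = 3)[lv]
    sw <- 0L
    if (nrow(ev) > 1)
      for (i in 2:nrow(ev))
        if (ev$drug[i] != ev$drug[i - 1] ||
            ev$dose_mg[i] != ev$dose_mg[i - 1]) sw <- sw + 1L
    keep <- !is.na(ord)
    o <- ord[keep]; dts <- ev$date[keep]
    modif <- "no_change"; tt <- followup
    if (length(o) > 1)
      for (i in 2:length(o))
        if (o[i] != o[i - 1]) {
          modif <- if (o[i] > o[i - 1]) "escalation" else "de_escalation"
          tt <- dts[i]
          break
        }
    list(modification = modif, switch_count = sw, time = tt)
  }
  set.seed(1)
  drugs <- c("atorvastatin", "rosuvastatin", "simvastatin", "pravastatin",
             "fluvastatin")
  doses <- c(5, 10, 20, 30, 40, 80)  # 30 mg is unclassifiable for most
  for (rep in 1:200) {
    k <- sample(1:6, 1)
    ev <- make_events(sort(sample(0:364, k)),
                      sample(drugs, k, replace = TRUE),
                      sample(doses, k, replace = TRUE))
    got <- derive_course(ev)
    want <- brute(ev)
    expect_identical(as.character(got$modification), want$modification)
    expect_identical(got$switch_count, want$switch_count)
    expect_identical(got$time_to_first_change, as.numeric(want$time))
  }
})

test_that("every subject gets exactly one modification class", {
  coh <- simulate_cohort(sim_config(n_subjects = 400, seed = 3))
  courses <- derive_courses(coh$dispensing)
  expect_identical(nrow(courses), 400L)
  expect_identical(sum(table(courses$modification)), 400L)
  expect_false(any(is.na(courses$modification)))
  expect_true(all(courses$time_to_first_change <= 365))
})

test_that("MPR arithmetic, bounds and the 80% adherence cutoff", {
  ev <- make_events(0, "atorvastatin", 20, supplied = 292)
  m <- compute_mpr(ev, 365)
  expect_equal(m$mpr, 0.8)
  expect_true(m$adherent)   # cutoff is inclusive

  ev$days_supplied <- 365
  expect_equal(compute_mpr(ev, 365)$mpr, 1)

  ev$days_supplied <- 180
  m <- compute_mpr(ev, 365)
  expect_equal(m$mpr, 180 / 365, tolerance = 1e-12)
  expect_false(m$adherent)

  expect_equal(compute_mpr(make_events(numeric(0), character(0),
                                       numeric(0)))$mpr, 0)

  # supply past follow-up end is truncated; mpr capped at 1
  ev <- make_events(c(0, 350), "atorvastatin", 20, supplied = c(365, 60))
  expect_equal(compute_mpr(ev, 365)$mpr, 1)

  # monotone non-decreasing in days supplied
  base <- make_events(c(0, 100), "atorvastatin", 20, supplied = c(50, 50))
  more <- base; more$days_supplied <- more$days_supplied + 20
  expect_gte(compute_mpr(more)$mpr, compute_mpr(base)$mpr)
})
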