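test_that("anthropometry validates its physiological ranges", {
  expect_error(anthropometry("male", 20, 1.8), "weight")
  expect_error(anthropometry("male", 80, 1.0), "height")
  a <- anthropometry("female", 65, 1.68, age_y = 40)
  expect_identical(a$sex, "female")
})

test_that("blood volumes follow the reference equations with liver at 13%", {
  a <- anthropometry("male", 80, 1.78)
  bv <- blood_volumes(a)
  # male: 0.3669 h^3 + 0.03219 w + 0.6041
  expect_equal(bv$total_L, 0.3669 * 1.78^3 + 0.03219 * 80 + 0.6041,
               tolerance = 1e-12)
  expect_equal(bv$liver_L / bv$total_L, 0.13, tolerance = 1e-12)
  f <- blood_volumes(anthropometry("female", 65, 1.68))
  expect_equal(f$total_L, 0.3561 * 1.68^3 + 0.03308 * 65 + 0.1833,
               tolerance = 1e-12)
  # the adjustment is bounded to +-30%
  expect_error(blood_volumes(a, adjustment = 1.4), "30%")
  expect_equal(blood_volumes(a, 1.2)$total_L, 1.2 * bv$total_L,
               tolerance = 1e-12)
})

test_that("the diabetes flag selects the T2D general-parameter set", {
  tw <- digital_twin(anthropometry("male", 90, 1.75, diabetes = TRUE))
  expect_identical(tw$variant, "t2d")
  expect_equal(unname(tw$params[["sec_rate"]]),
               unname(default_params("t2d")[["sec_rate"]]))
  expect_equal(tw$personal[["basal_glucose"]],
               personal_defaults("t2d")[["basal_glucose"]])
})

test_that("calibrating to basal values hits the baselines", {
  cb <- calibrate_basal(digital_twin(),
                        list(glucose = 4.6, hepatic_glycogen = 300))
  # the basal-glucose parameter is recovered exactly (well within 2%)
  expect_equal(cb$twin$personal[["basal_glucose"]], 4.6)
  st <- steady_state(personal = cb$twin$personal)
  expect_equal(st[["glc_plasma"]], 4.6, tolerance = 1e-9)
  # the lead-in diet lands the glycogen store near the fed baseline
  expect_lt(abs(cb$achieved[["hepatic_glycogen"]] - 300), 0.05 * 300 + 15)
  expect_true(cb$achieved[["hepatic_glycogen"]] >= 200 &&
                cb$achieved[["hepatic_glycogen"]] <= 350)
  # meal sizes respect the 200-1000 kcal bound
  expect_true(all(cb$lead_in$kcal >= 200 & cb$lead_in$kcal <= 1000))
  expect_error(calibrate_basal(digital_twin(), list(insulin = 40)),
               "glucose")
})

test_that("noise-free self-calibration returns unit modifiers", {
  tw <- digital_twin()
  spec <- fixture_spec(schedule = diet_schedule(meal_event(1, carb_g = 60,
                                                           protein_g = 20)),
                       t_span_h = c(0, 6), times_h = seq(1, 5, 1),
                       sigma = c(plasma_glucose = 1e-6,
                                 plasma_insulin = 1e-4), seed = 3)
  ds <- generate_study(spec)
  fp <- fit_person_params(tw, ds, maxit = 60)
  expect_equal(unname(fp$modifiers), c(1, 1, 1), tolerance = 0.02)
  expect_lt(fp$cost, 1)
})

test_that("personalisation never touches the 57 general parameters", {
  tw <- digital_twin()
  before <- tw$params
  ds <- small_fixture()
  fp <- fit_person_params(tw, ds, maxit = 10)
  expect_identical(fp$twin$params, before)
  cb <- calibrate_basal(tw, list(glucose = 5.2))
  expect_identical(cb$twin$params, before)
})

test_that("modifier round-trips recover within 10% median error", {
  # the third calibration category: 20 synthetic subjects with known
  # production/clearance/resistance modifiers, refit from noisy data
  tw <- digital_twin()
  sched <- diet_schedule(meal_event(1, carb_g = 75, protein_g = 25))
  obs <- c("plasma_glucose", "plasma_insulin", "EGP")
  sim0 <- simulate_twin(sched, c(0, 6.5))
  sig <- sapply(obs, function(k)
    0.05 * mean(observable_map(sim0, k)$value))
  errs <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    set.seed(2000 + s)
    truth <- c(runif(1, 0.7, 1.4), runif(1, 0.6, 1.3),
               runif(1, 0.7, 1.4))
    pers <- tw$personal
    pers[c("prod_mod", "clear_mod", "resist_mod")] <- truth
    ds <- generate_study(fixture_spec(
      personal = pers, schedule = sched, t_span_h = c(0, 6.5),
      times_h = seq(0.5, 6, by = 0.55), observables = obs, sigma = sig,
      n = 1, seed = s))
    fp <- fit_person_params(tw, ds, grid_min = 5, rtol = 1e-4,
                            maxit = 70)
    errs[s, ] <- abs(fp$modifiers - truth) / truth
  }
  expect_lt(median(errs), 0.10)
})

test_that("subject profiles load from YAML", {
  f <- system.file("extdata", "subject_example.yaml", package = "metabtwin")
  tw <- read_subject(f)
  expect_equal(tw$anthro$weight_kg, 80)
  expect_identical(tw$variant, "healthy")
  expect_equal(tw$personal[["basal_glucose"]], 5.0)
})
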