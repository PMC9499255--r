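test_that("sem is sigma over root n", {
  expect_equal(sem(2, 4), 1)
  expect_equal(sem(3, 9), 1)
  expect_equal(sem(0, 5), 0)
  expect_error(sem(1, 0), ">= 1")
})

test_that("chi-squared thresholds reproduce the analytic quantiles", {
  expect_equal(round(chi2_threshold(0.05, 126)), 153)
  expect_equal(round(chi2_threshold(0.05, 190)), 223)
  expect_equal(round(chi2_threshold(0.05, 83)), 105)
  expect_equal(round(chi2_threshold(0.05, 14)), 24)
  expect_equal(round(chi2_threshold(0.05, 35)), 50)
  expect_equal(round(chi2_threshold(0.05, 44)), 60)
  expect_error(chi2_threshold(1.5, 10), "alpha")
  expect_error(chi2_threshold(0.05, 0), "dof")
})

test_that("the acceptance test passes and fails where it should", {
  expect_true(chi2_test(175, 190)$pass)
  expect_false(chi2_test(300, 190)$pass)
  expect_true(chi2_test(61, 83)$pass)
  expect_true(chi2_test(16, 14)$pass)
})

test_that("the weighted least-squares cost matches hand arithmetic", {
  sim <- meal_sim()
  g2 <- approx(sim$time_h, sim$state[, "glc_plasma"], xout = 2)$y
  # one record, residual = 2 SEM -> cost 4
  ds <- study_dataset(data.frame(time_h = 2, observable = "plasma_glucose",
                                 value = g2 + 2, sd = 2, n = 4),
                      schedule = meal_schedule(), t_span_h = c(0, 10))
  expect_equal(wls_cost(ds, sim, sem_floor_frac = 0), 4, tolerance = 1e-9)
  # a perfect fit costs zero; N unit residuals cost N
  times <- c(1, 2, 3, 5)
  gv <- approx(sim$time_h, sim$state[, "glc_plasma"], xout = times)$y
  ds0 <- study_dataset(data.frame(time_h = times,
                                  observable = "plasma_glucose",
                                  value = gv, sd = 1, n = 1),
                       schedule = meal_schedule(), t_span_h = c(0, 10))
  expect_equal(wls_cost(ds0, sim, sem_floor_frac = 0), 0, tolerance = 1e-9)
  ds1 <- study_dataset(data.frame(time_h = times,
                                  observable = "plasma_glucose",
                                  value = gv + 1, sd = 1, n = 1),
                       schedule = meal_schedule(), t_span_h = c(0, 10))
  expect_equal(wls_cost(ds1, sim, sem_floor_frac = 0), 4, tolerance = 1e-9)
})

test_that("study datasets validate and round-trip through CSV", {
  ds <- small_fixture()
  expect_equal(ds$records$sem, ds$records$sd / sqrt(ds$records$n))
  f <- tempfile(fileext = ".csv")
  write_study(ds, f)
  ds2 <- read_study(f, schedule = ds$schedule, t_span_h = ds$t_span_h)
  expect_equal(ds2$records$value, ds$records$value, tolerance = 1e-9)
  expect_equal(ds2$population, "healthy")
  expect_error(study_dataset(data.frame(time_h = 1, observable = "x",
                                        value = 1, sd = 1, n = 1),
                             t_span_h = c(0, 0.5)), "outside")
})

test_that("the eight qualitative constraints hold for the shipped defaults", {
  sim48 <- fast48_sim()
  pen_fast <- evaluate_penalties(sim48, unfed_h = 48,
                                 postabs_window_h = c(10, 14))
  expect_equal(pen_fast$penalty, 0)
  expect_true(all(pen_fast$report$ok, na.rm = TRUE))

  simday <- standard_day_sim()
  pen_day <- evaluate_penalties(simday, fed_h = c(22, 46),
                                postprandial_window_h = c(13, 16))
  expect_equal(pen_day$penalty, 0)
  expect_true(all(pen_day$report$ok, na.rm = TRUE))

  # the diabetic defaults satisfy them too
  pen_t2d <- evaluate_penalties(t2d_fast_sim(), unfed_h = 48,
                                postabs_window_h = c(10, 14))
  expect_equal(pen_t2d$penalty, 0)
})

test_that("violations are flagged with a constant penalty each", {
  sim <- fast48_sim()
  doctored <- sim
  doctored$state[5, "ins_plasma"] <- 3500
  pen <- evaluate_penalties(doctored)
  expect_false(pen$report$ok[2])
  expect_equal(pen$penalty, 1e5)
  # an impossible renal share trips constraint 3
  d2 <- sim
  d2$flux$glycogenolysis_kidney <- d2$flux$glycogenolysis_liver * 2
  pen2 <- evaluate_penalties(d2)
  expect_false(pen2$report$ok[3])
  expect_gte(pen2$penalty, 1e5)
})

test_that("fit_global is deterministic, bounded and archives an ensemble", {
  ds <- small_fixture()
  f1 <- fit_global(list(ds), free = c("vm_muscle", "k_gastric_carb"),
                   swarm_size = 8, max_iter = 6, penalty_sims = FALSE,
                   seed = 3)
  f2 <- fit_global(list(ds), free = c("vm_muscle", "k_gastric_carb"),
                   swarm_size = 8, max_iter = 6, penalty_sims = FALSE,
                   seed = 3)
  expect_identical(f1$best_cost, f2$best_cost)
  expect_identical(f1$best, f2$best)
  b <- param_bounds()
  lb <- b$lower[match(names(f1$best), b$name)]
  ub <- b$upper[match(names(f1$best), b$name)]
  expect_true(all(f1$best >= lb & f1$best <= ub))
  # self-consistency: fixture generated from the defaults passes chi-squared
  expect_true(f1$chi2$pass)
  expect_gt(nrow(f1$ensemble), 0)
  expect_true(all(f1$ensemble_cost <= f1$threshold))
  expect_error(fit_global(list(ds), free = "no_such_param"), "unknown")
})

test_that("ensemble bands envelope the best trajectory and never narrow", {
  ds <- small_fixture()
  fit <- fit_global(list(ds), free = "vm_muscle", swarm_size = 6,
                    max_iter = 4, penalty_sims = FALSE, seed = 5)
  bands <- ensemble_bands(fit, ds$schedule, ds$t_span_h,
                          observables = "plasma_glucose", grid_min = 10)
  expect_true(all(bands$lower <= bands$best + 1e-6))
  expect_true(all(bands$best <= bands$upper + 1e-6))
  # a singleton ensemble collapses to its own trajectory
  fit1 <- fit
  fit1$ensemble <- fit$ensemble[1, , drop = FALSE]
  b1 <- ensemble_bands(fit1, ds$schedule, ds$t_span_h,
                       observables = "plasma_glucose", grid_min = 10)
  expect_equal(b1$lower, b1$upper, tolerance = 1e-9)
  # enlarging the ensemble can only widen the envelope
  expect_true(all(b1$lower >= bands$lower - 1e-9))
  expect_true(all(b1$upper <= bands$upper + 1e-9))
  fit0 <- fit; fit0$ensemble <- fit$ensemble[0, , drop = FALSE]
  expect_error(ensemble_bands(fit0), "empty")
})

test_that("penalties never contaminate the chi-squared verdict", {
  ds <- small_fixture()
  sim <- simulate_twin(ds$schedule, ds$t_span_h)
  plain_cost <- wls_cost(ds, sim)
  # the verdict recomputed without penalties matches the archived cost
  fit <- fit_global(list(ds), free = "vm_muscle", swarm_size = 4,
                    max_iter = 2, penalty_sims = TRUE, seed = 9)
  expect_equal(fit$chi2$cost, fit$best_cost)
  expect_true(is.finite(plain_cost))
})
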