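test_that("the parameter tables have the documented structure", {
  p <- default_params()
  expect_length(p, 57)
  expect_true(all(p > 0))
  b <- param_bounds()
  expect_true(all(b$lower <= b$default & b$default <= b$upper))
  expect_silent(validate_params(p))
  t2 <- default_params("t2d")
  expect_length(t2, 57)
  expect_false(all(t2 == p))  # the variants differ
  expect_length(personal_defaults(), 5)
  expect_error(validate_personal(c(basal_glucose = 20, basal_insulin = 40,
                                   prod_mod = 1, clear_mod = 1,
                                   resist_mod = 1)), "basal glucose")
  bad <- p; bad[["vm_muscle"]] <- b$upper[b$name == "vm_muscle"] * 2
  expect_error(validate_params(bad), "bounds")
})

test_that("the basal state is a fixed point of the fast subsystems", {
  pc <- model_context()
  d <- metab_rhs(0, pc$init, pc)[[1]]
  names(d) <- names(pc$init)
  fast_states <- c("glc_plasma", "glc_tissue", "ins_plasma", "ins_liver",
                   "g6p_liver", "aa_liver", "pyruvate_liver", "tca_liver")
  expect_true(all(abs(d[fast_states]) < 1e-8))
  # the stores are slow, not stationary: glycogen drains post-absorptively
  expect_lt(d[["glycogen_liver"]], 0)
})

test_that("steady_state honours its basal targets and the fed window", {
  st <- steady_state(glycogen = 275)
  expect_equal(st[["glc_plasma"]], 5.0)
  expect_equal(st[["ins_plasma"]], 40)
  expect_true(st[["glycogen_liver"]] >= 200 && st[["glycogen_liver"]] <= 350)
  # a requested basal glucose propagates exactly
  pers <- personal_defaults(); pers[["basal_glucose"]] <- 4.6
  st2 <- steady_state(personal = pers)
  expect_equal(st2[["glc_plasma"]], 4.6)
  # one simulated hour drifts less than 0.05 mmol/L
  s1 <- simulate_twin(t_span_h = c(0, 1))
  expect_lt(abs(s1$state[nrow(s1$state), "glc_plasma"] -
                  s1$state[1, "glc_plasma"]), 0.05)
})

test_that("empty stores produce no glycogenolysis flux", {
  pc <- model_context()
  st <- pc$init
  st[["glycogen_liver"]] <- 0
  st[["glycogen_kidney"]] <- 0
  st[["stomach_carb"]] <- 0; st[["gut_glucose"]] <- 0
  f <- metabtwin:::.model_fluxes(0, st, pc)
  expect_equal(f[["glycogenolysis_liver"]], 0)
  expect_equal(f[["glycogenolysis_kidney"]], 0)
})

test_that("raising the insulin-resistance modifier lowers insulin-dependent uptake", {
  pers2 <- personal_defaults(); pers2[["resist_mod"]] <- 2
  pc1 <- model_context()
  pc2 <- model_context(personal = pers2)
  st <- pc1$init
  st[["ins_plasma"]] <- 200; st[["ins_liver"]] <- 300  # fed-level insulin
  f1 <- metabtwin:::.model_fluxes(0, st, pc1)
  f2 <- metabtwin:::.model_fluxes(0, st, pc2)
  expect_lt(f2[["u_muscle"]], f1[["u_muscle"]])
  expect_lt(f2[["u_liver"]], f1[["u_liver"]])
})

test_that("raising insulin never increases gluconeogenesis or glycogenolysis", {
  pc <- model_context()
  st <- pc$init
  lvls <- c(40, 100, 300, 900)
  gng <- gl <- numeric(length(lvls))
  for (i in seq_along(lvls)) {
    st[["ins_plasma"]] <- lvls[i]; st[["ins_liver"]] <- lvls[i]
    f <- metabtwin:::.model_fluxes(0, st, pc)
    gng[i] <- f[["gng_liver"]] + f[["gng_kidney"]]
    gl[i] <- f[["glycogenolysis_liver"]] + f[["glycogenolysis_kidney"]]
  }
  expect_true(all(diff(gng) <= 1e-12))
  expect_true(all(diff(gl) <= 1e-12))
})

test_that("meal input mass is conserved through the gut", {
  sim <- meal_sim()
  n <- nrow(sim$state)
  expect_equal(unname(sim$state[n, "carb_absorbed"]), 87,
               tolerance = 1e-3)
  expect_equal(unname(sim$state[n, "protein_absorbed"]), 23,
               tolerance = 2e-3)
})

test_that("states stay non-negative and finite on all fixture protocols", {
  for (sim in list(fast48_sim(), meal_sim(), standard_day_sim(),
                   t2d_fast_sim())) {
    expect_true(all(is.finite(sim$state)))
    expect_gte(min(sim$state), -1e-9)
    expect_false(sim$negative_states)
  }
})

test_that("a 48 h fast depletes glycogen and lowers glucose", {
  sim <- fast48_sim()
  g <- sim$state[, "glc_plasma"]; gl <- sim$state[, "glycogen_liver"]
  th <- sim$time_h
  # hepatic glycogen non-increasing under zero input
  expect_true(all(diff(gl) <= 1e-6))
  # glucose at 48 h strictly below its 12 h value
  expect_lt(g[which.min(abs(th - 48))], g[which.min(abs(th - 12))])
  expect_lt(gl[which.min(abs(th - 48))], 100)
})

test_that("the adaptive solution matches a fixed-step reference within 0.5%", {
  ctx <- model_context(schedule = meal_schedule())
  sa <- simulate_twin(meal_schedule(), c(0, 10), context = ctx)
  sf <- simulate_fixed_step(meal_schedule(), c(0, 10), context = ctx,
                            step_min = 0.25)
  for (v in c("glc_plasma", "ins_plasma", "glycogen_liver")) {
    ya <- approx(sa$time_h, sa$state[, v], xout = sf$time_h)$y
    rel <- abs(ya - sf$state[, v]) / pmax(abs(ya), 1e-9)
    expect_lt(max(rel, na.rm = TRUE), 0.005)
  }
})

test_that("simulation guards reject bad inputs", {
  expect_error(simulate_twin(t_span_h = c(10, 2)), "increasing")
  expect_error(simulate_twin(meal_schedule(), t_span_h = c(0, 0.5)),
               "cover")
  pc <- model_context()
  bad <- pc$init; bad[1] <- NaN
  expect_error(metab_rhs(0, bad, pc), "non-finite")
  expect_warning(simulate_twin(
    diet_schedule(meal_event(1, carb_g = 200, fat_g = 60)),
    t_span_h = c(0, 8)), "1000 kcal")
})

test_that("tidy export aligns with the simulation grid", {
  sim <- meal_sim()
  df <- as.data.frame(sim)
  expect_true(all(c("time_h", "variable", "value") %in% names(df)))
  g <- df[df$variable == "glc_plasma", ]
  expect_equal(g$value, unname(sim$state[, "glc_plasma"]))
  expect_true(all(diff(sim$time_h) > 0))
})
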