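test_that("meal construction enforces the Atwater energy closure", {
  m <- meal_event(1, carb_g = 87, protein_g = 23, fat_g = 10)
  expect_equal(m$kcal, 4 * 87 + 4 * 23 + 9 * 10)
  expect_error(meal_event(1, carb_g = 87, protein_g = 23, kcal = 300),
               "close")
  expect_error(meal_event(1, carb_g = -1), ">= 0")
  expect_error(meal_event(1, duration_min = 0), "> 0")
})

test_that("meal_from_energy infers fat from the energy closure", {
  # 940 kcal meal with 81 g carbohydrate and 41 g protein
  m <- meal_from_energy(940, carb_g = 81, protein_g = 41)
  expect_equal(m$fat_g, (940 - 4 * 81 - 4 * 41) / 9, tolerance = 1e-12)
  expect_equal(round(m$fat_g, 1), 50.2)
  # the 132.5 kcal protein bolus
  b <- meal_from_energy(132.5, carb_g = 2.6, protein_g = 25.55)
  expect_equal(round(b$fat_g, 2), 2.21)
  # empty meal is valid
  z <- meal_from_energy(0, 0, 0)
  expect_equal(z$fat_g, 0)
  expect_error(meal_from_energy(100, carb_g = 50, protein_g = 0),
               "implied fat")
})

test_that("diet schedules reject overlapping meals and stay ordered", {
  expect_error(diet_schedule(meal_event(1, carb_g = 10, duration_min = 120),
                             meal_event(1.5, carb_g = 10)), "overlap")
  s <- diet_schedule(meal_event(8, carb_g = 10), meal_event(1, carb_g = 5))
  expect_equal(s$start_h, c(1, 8))
})

test_that("the 5:2 template is isocaloric at the weekly level", {
  wk <- build_diet("5:2", daily_kcal = 2000, days = 7)
  days <- floor(wk$start_h / 24)
  daily <- as.numeric(tapply(wk$kcal, days, sum))
  expect_equal(daily[1:5], rep(2560, 5), tolerance = 1e-9)
  expect_equal(daily[6:7], rep(600, 2), tolerance = 1e-9)
  expect_equal(weekly_mean_kcal(wk), 2000, tolerance = 1e-9)
})

test_that("isocaloric schemes agree in weekly energy to 0.1%", {
  kcals <- vapply(c("IF", "5:2", "SFM"), function(s)
    weekly_mean_kcal(build_diet(s, daily_kcal = 2000, days = 7)), 0)
  expect_true(all(abs(kcals - 2000) / 2000 < 1e-3))
})

test_that("scheme macronutrient splits match their definitions", {
  # 2000 kcal/day at 45% carbohydrate = 225 g/day
  s <- build_diet("IF", daily_kcal = 2000, days = 1,
                  macro_split = c(carb = 45, protein = 27.5, fat = 27.5))
  expect_equal(sum(s$carb_g), 0.45 * 2000 / 4, tolerance = 1e-9)
  hc <- build_diet("HCLF", daily_kcal = 2000, days = 1)
  lc <- build_diet("LCHF", daily_kcal = 2000, days = 1)
  expect_equal(sum(hc$carb_g), 0.60 * 2000 / 4, tolerance = 1e-9)
  # LCHF carries half the HCLF carbohydrate
  expect_equal(sum(lc$carb_g), sum(hc$carb_g) / 2, tolerance = 1e-9)
  # IF: two meals of 1000 kcal at the 2000 kcal/day target
  i2 <- build_diet("IF", daily_kcal = 2000, days = 1)
  expect_equal(nrow(i2), 2)
  expect_equal(i2$kcal, c(1000, 1000), tolerance = 1e-9)
})

test_that("the input signal conserves meal mass", {
  s <- diet_schedule(meal_event(1, carb_g = 87, protein_g = 23,
                                duration_min = 15))
  u <- to_input_signal(s)
  # square pulse: 87 g over 15 min = 5.8 g/min
  expect_equal(u$rate(65)[["carb"]], 87 / 15)
  expect_equal(u$rate(0)[["carb"]], 0)
  expect_equal(u$rate(80)[["carb"]], 0)
  # integral equals grams; halving duration doubles rate
  s2 <- diet_schedule(meal_event(1, carb_g = 87, duration_min = 7.5))
  u2 <- to_input_signal(s2)
  expect_equal(u2$rate(62)[["carb"]], 2 * u$rate(62)[["carb"]])
  expect_equal(u$rate(62)[["carb"]] * 15, u2$rate(62)[["carb"]] * 7.5)
  # empty schedule: identically zero
  u0 <- to_input_signal(diet_schedule())
  expect_equal(unname(u0$rate(100)), c(0, 0, 0))
})

test_that("schedules round-trip through YAML", {
  s <- build_diet("SFM", daily_kcal = 1800, days = 2)
  f <- tempfile(fileext = ".yaml")
  write_schedule(s, f)
  s2 <- read_schedule(f)
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-6)
  expect_equal(attr(s2, "scheme"), "SFM")
})

test_that("bundled diet templates load and are isocaloric where stated", {
  dir <- system.file("extdata", "diets", package = "metabtwin")
  for (f in c("IF_week.yaml", "52_week.yaml", "SFM_week.yaml")) {
    s <- read_schedule(file.path(dir, f))
    expect_equal(weekly_mean_kcal(s), 2000, tolerance = 2)
  }
})
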