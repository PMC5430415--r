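test_that("weekly interpolation preserves constants and conserves totals", {
  expect_equal(interpolateWeekly(rep(17.3, 12)), rep(17.3, 52))
  for (prcp in list(rep(100, 12), 1:12 * 10, c(0, 0, 500, rep(1, 9)))) {
    expect_equal(sum(interpolateWeekly(prcp, "total")), sum(prcp),
                 tolerance = 1e-12)
  }
  expect_error(interpolateWeekly(c(rep(1, 11), NA)), "finite")
  expect_error(interpolateWeekly(1:10), "12")
})

test_that("rate interpolation matches a hand-worked sawtooth at the December midpoint", {
  # months all 0 except December = 12; month midpoints sit at
  # (m - 0.5) * 52/12 weeks, so the December peak lies between the
  # centers of weeks 50 and 51; linear interpolation by hand gives
  # 12 * 12/13 and 12 * 11/13 there.
  w <- interpolateWeekly(c(rep(0, 11), 12))
  expect_equal(w[50], 144 / 13, tolerance = 1e-12)
  expect_equal(w[51], 132 / 13, tolerance = 1e-12)
  # far from December the series is exactly zero
  expect_equal(w[10:40], rep(0, 31))
})

test_that("temperature response is the fitted trapezoid", {
  p <- defaultFornicatusParams()
  expect_equal(temperatureIndex(15, p), 0)       # below threshold: no survival
  expect_equal(temperatureIndex(c(26, 30, 35), p), c(1, 1, 1))  # optimum range
  expect_equal(temperatureIndex(20.5, p), 0.5)   # midpoint of 15 -> 26
  expect_equal(temperatureIndex(37.5, p), 0.5)   # midpoint of 35 -> 40
  expect_equal(temperatureIndex(c(-10, 40, 60), p), c(0, 0, 0))
})

test_that("moisture response hits the fitted soil-moisture knots", {
  p <- defaultFornicatusParams()
  expect_equal(moistureIndex(c(0.05, 0.3, 1, 2.5), p), c(0, 1, 1, 0))
  expect_equal(moistureIndex(0.175, p), 0.5)
  expect_equal(moistureIndex(1.75, p), 0.5)
})

test_that("evaporative demand follows its closed form", {
  expect_equal(weeklyEvaporation(10, 50, 50), 0.8 * 10 * 0.5 * 7)  # = 28
  expect_equal(weeklyEvaporation(-5, 40, 40), 0)   # frozen: no demand
  expect_equal(weeklyEvaporation(25, 100, 100), 0) # saturated air
  expect_equal(weeklyEvaporation(10, 50, 50, k = 0.4), 14)
})

test_that("bucket step balances, floors at zero and rejects bad capacity", {
  expect_equal(updateSoilMoisture(0.4, 25, 25, 100), 0.4)
  expect_equal(updateSoilMoisture(0.1, 0, 500, 100), 0)
  expect_equal(updateSoilMoisture(3.4, 100, 0, 100, smCap = 3.5), 3.5)
  expect_error(updateSoilMoisture(0.5, 10, 10, 0), "capacity")
})

test_that("bucket spin-up saturates under sustained surplus and is init-independent", {
  rain <- rep(20, 52); demand <- rep(10, 52)
  sm <- spinUpSoilMoisture(rain, demand, capacity = 100, smCap = 3.5)
  expect_equal(sm, rep(3.5, 52))    # inflow exceeds the largest outflow
  # steady state does not depend on where the bucket starts
  for (init in c(0, 0.7, 3.5)) {
    smi <- spinUpSoilMoisture(rep(30, 52), rep(60, 52), smInit = init)
    expect_equal(smi, rep(0.5, 52), tolerance = 1e-5)  # rain/demand balance
  }
})

test_that("stress accumulation matches its closed form and caps at 100", {
  expect_equal(accumulateStress(rep(5, 52), -10, -0.005, "below"), 0)
  # 2 degrees below -10 every week at |rate| 0.005: 100*52*0.005*2 = 52
  expect_equal(accumulateStress(rep(-12, 52), -10, -0.005, "below"), 52)
  expect_equal(accumulateStress(rep(-60, 52), -10, -0.005, "below"), 100)
  expect_equal(accumulateStress(rep(45, 52), 42, 0.0002, "above"),
               100 * 52 * 0.0002 * 3)
  expect_error(accumulateStress(c(rep(0, 51), NA), 0, 1), "finite")
})

test_that("stress survival product follows its defining identity", {
  expect_equal(annualStressIndex(0, 0, 0, 0), 1)
  expect_equal(annualStressIndex(100, 0, 0, 0), 0)
  expect_equal(annualStressIndex(50, 50, 0, 0), 0.25)
  expect_error(annualStressIndex(101, 0, 0, 0), "\\[0, 100\\]")
})

test_that("degree-days and generations follow the development threshold", {
  p <- defaultFornicatusParams()
  at <- degreeDayGenerations(rep(15, 52), p)
  expect_equal(at$ddAnnual, 0)
  expect_equal(at$generations, 0)
  warm <- degreeDayGenerations(rep(25, 52), p)
  expect_equal(warm$ddAnnual, 10 * 7 * 52)          # 3640 DD
  expect_equal(warm$generations, 3640 / 373)        # ~9.76 generations
  expect_true(is.na(degreeDayGenerations(rep(25, 52),
                                         wetTropicalTemplate())$generations))
})

test_that("annual growth index averages the weekly growth product", {
  expect_equal(annualGrowthIndex(rep(1, 52), rep(1, 52)), 100)
  expect_equal(annualGrowthIndex(rep(0, 52), rep(1, 52)), 0)
  expect_equal(annualGrowthIndex(rep(1, 52), rep(c(1, 0), each = 26)), 50)
})

test_that("an ideal warm wet climate is highly favourable with no stress", {
  r <- runLocation(constantClimate(), defaultFornicatusParams())
  expect_equal(r@cs + r@hs, 0)
  expect_gt(r@giA, 99)
  expect_gt(r@ei, 20)
  # regression anchor from the first verified run of this configuration
  expect_equal(r@ei, 100, tolerance = 1e-6)
})

test_that("limiting conditions force EI to zero with the right flag", {
  p <- defaultFornicatusParams()
  frozen <- constantClimate(tmax = -50, tmin = -60, prcp = 30)
  rf <- runLocation(frozen, p)
  expect_equal(rf@cs, 100)
  expect_equal(rf@si, 0)
  expect_equal(rf@ei, 0)
  expect_true(all(c("CS_GE_100", "TI_ZERO", "GEN_LT_1") %in% rf@limitingFlags))

  cool <- constantClimate(tmax = 20, tmin = 10)   # tavg at the threshold
  rc <- runLocation(cool, p)
  expect_equal(rc@generations, 0)
  expect_equal(rc@ei, 0)
  expect_true("GEN_LT_1" %in% rc@limitingFlags)

  dry <- constantClimate(prcp = 0, rh09 = 30, rh15 = 20)
  rd <- runLocation(dry, p)
  expect_true("MI_ZERO" %in% rd@limitingFlags)
  expect_equal(rd@ei, 0)
})

test_that("EI equals GI_A when stress-free and above one generation", {
  r <- runLocation(constantClimate(), defaultFornicatusParams())
  expect_equal(r@ei, r@giA * r@si, tolerance = 1e-12)
  expect_equal(r@si, 1, tolerance = 1e-9)
  expect_equal(r@ei, r@giA, tolerance = 1e-6)
})

test_that("EI stays in [0,100] across randomized climates", {
  set.seed(101)
  p <- defaultFornicatusParams()
  for (i in 1:40) {
    tmin <- runif(12, -30, 25)
    dtr <- runif(12, 2, 15)
    mc <- MonthlyClimate(tmax = tmin + dtr, tmin = tmin,
                         prcp = runif(12, 0, 400),
                         rh09 = runif(12, 20, 100),
                         rh15 = runif(12, 10, 90))
    r <- runLocation(mc, p)
    expect_gte(r@ei, 0); expect_lte(r@ei, 100)
    expect_gte(r@giA, 0); expect_lte(r@giA, 100)
    expect_true(all(r@weekly$ti >= 0 & r@weekly$ti <= 1))
    expect_true(all(r@weekly$mi >= 0 & r@weekly$mi <= 1))
    expect_true(all(r@weekly$sm >= 0))
    if (length(r@limitingFlags)) expect_equal(r@ei, 0)
  }
})

test_that("engine matches the independent hand computation on constant climates", {
  p <- defaultFornicatusParams()
  cases <- list(
    c(tmax = 35, tmin = 25, prcp = 150, rh09 = 80, rh15 = 60),  # ideal
    c(tmax = 30, tmin = 20, prcp = 60, rh09 = 60, rh15 = 40),   # semi-arid
    c(tmax = 22, tmin = 12, prcp = 90, rh09 = 70, rh15 = 50),   # cool
    c(tmax = 45, tmin = 33, prcp = 200, rh09 = 70, rh15 = 50),  # hot
    c(tmax = 28, tmin = 18, prcp = 10, rh09 = 40, rh15 = 25)    # dry
  )
  for (cs in cases) {
    mc <- constantClimate(cs["tmax"], cs["tmin"], cs["prcp"],
                          cs["rh09"], cs["rh15"])
    r <- runLocation(mc, p)
    expect_equal(r@ei,
                 oracleEi(cs[["tmax"]], cs[["tmin"]], cs[["prcp"]],
                          cs[["rh09"]], cs[["rh15"]], p),
                 tolerance = 1e-9, label = paste(cs, collapse = "/"))
  }
})

test_that("raising the development threshold never raises EI", {
  set.seed(202)
  p <- defaultFornicatusParams()
  for (i in 1:5) {
    tmin <- runif(12, 0, 22)
    mc <- MonthlyClimate(tmax = tmin + 10, tmin = tmin,
                         prcp = runif(12, 30, 250),
                         rh09 = runif(12, 40, 95), rh15 = runif(12, 30, 85))
    eis <- vapply(c(13, 15, 17, 19, 21), function(dv0) {
      runLocation(mc, updateParams(p, dv0 = dv0))@ei
    }, numeric(1))
    expect_true(all(diff(eis) <= 1e-12))
  }
})

test_that("soil-moisture spin-up result is independent of the initial state", {
  set.seed(303)
  rain <- matrix(runif(52 * 3, 0, 60), 52)
  demand <- matrix(runif(52 * 3, 5, 60), 52)
  a <- spinUpSoilMoisture(rain, demand, smInit = 0)
  b <- spinUpSoilMoisture(rain, demand, smInit = 3.2)
  expect_equal(a, b, tolerance = 1e-5)
})
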