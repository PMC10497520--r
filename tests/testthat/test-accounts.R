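fake_solution <- function(world, production) {
  structure(list(year = 2020, production = production,
                 alt_ingredient_use = matrix(
                   0, nrow(production), 18,
                   dimnames = list(rownames(production), fs_crops()))),
            class = "fs_equilibrium")
}

test_that("agricultural emissions scale with activity", {
  w <- small_world()
  sol <- w$base_state$solution
  led <- agricultural_emissions(sol, w)
  expect_true(all(led$value >= 0))
  # independent recomputation of enteric CH4 (intensity 1 at the base year)
  ent <- led[led$source == "enteric_fermentation", ]
  xa <- sol$production[, fs_animal_products()]
  expected <- rowSums(xa * w$calib$ef_enteric) * w$calib$gwp_ch4
  expect_equal(ent$value, unname(expected[ent$region]), tolerance = 1e-10)
  # zero production -> all-zero ledger
  x0 <- sol$production; x0[] <- 0
  led0 <- agricultural_emissions(fake_solution(w, x0), w)
  expect_true(all(led0$value == 0))
  # halved ruminant output at fixed intensity halves enteric CH4
  xh <- sol$production
  xh[, fs_animal_products()] <- xh[, fs_animal_products()] / 2
  ledh <- agricultural_emissions(fake_solution(w, xh), w)
  expect_equal(ledh$value[ledh$source == "enteric_fermentation"],
               ent$value / 2, tolerance = 1e-10)
})

test_that("gases aggregate to CO2eq with GWP100 constants", {
  w <- small_world()
  # 1 Mt CH4 at GWP100 28 is 28 Mt CO2eq: force a single unit activity
  w2 <- w
  w2$calib$ef_enteric[] <- 0
  w2$calib$ef_enteric["BRA", "beef"] <- 1      # t CH4 per t product
  x <- w$base_state$solution$production
  x[] <- 0
  x["BRA", "beef"] <- 1                         # Mt
  led <- agricultural_emissions(fake_solution(w2, x), w2)
  expect_equal(sum(led$value[led$source == "enteric_fermentation"]), 28)
  expect_equal(sum(led$value[led$gas == "CH4" &
                               led$source == "rice_cultivation"]), 0)
})

test_that("land-use-change CO2 uses stock differences over the step", {
  stocks <- matrix(c(150, 10, 40, 10, 10, 150), 1, 6,
                   dimnames = list("R1", c("forest", "cropland",
                                           "other_natural", "grassland",
                                           "abandoned", "restored")))
  none <- data.frame(region = character(), from = character(),
                     to = character(), area = numeric())
  expect_equal(unname(land_use_change_co2(none, stocks)["R1"]), 0)
  one <- data.frame(region = "R1", from = "forest", to = "cropland",
                    area = 1)
  # 1 Mha x 140 t C/ha = 140 Mt C -> 513.33 Mt CO2 over the decade
  expect_equal(unname(land_use_change_co2(one, stocks)["R1"]) * 10,
               140 * 44 / 12, tolerance = 1e-10)
  # equal and opposite transitions net to zero
  pair <- data.frame(region = "R1",
                     from = c("grassland", "cropland"),
                     to = c("cropland", "grassland"), area = 2)
  expect_equal(unname(land_use_change_co2(pair, stocks)["R1"]), 0)
  # abandonment is carbon-neutral
  ab <- data.frame(region = "R1", from = "cropland", to = "abandoned",
                   area = 5)
  expect_equal(unname(land_use_change_co2(ab, stocks)["R1"]), 0)
  bad <- data.frame(region = "R1", from = "swamp", to = "cropland",
                    area = 1)
  expect_error(land_use_change_co2(bad, stocks), "accounting error")
})

test_that("nitrogen inputs follow harvested N, NUE and manure rules", {
  w <- small_world()
  w2 <- w
  w2$calib$n_harvest[] <- 0.02
  w2$calib$n_nue[] <- 0.5
  x <- w$base_state$solution$production
  x[] <- 0
  x["BRA", "wheat"] <- 2500        # harvested N = 50 Mt
  n <- nitrogen_inputs(fake_solution(w2, x), w2)
  expect_equal(n$total_n_input[n$region == "BRA"], 100)   # 50 / 0.5
  expect_equal(sum(n$manure_n_applied), 0)                # no livestock
  w2$calib$n_nue[] <- 1
  n1 <- nitrogen_inputs(fake_solution(w2, x), w2)
  expect_equal(n1$total_n_input[n1$region == "BRA"], 50)  # identity at NUE 1
  w2$calib$n_nue[] <- 0
  expect_error(nitrogen_inputs(fake_solution(w2, x), w2), "accounting error")
})

test_that("water use is linear with unit conversion to km3", {
  w <- small_world()
  x <- w$base_state$solution$production
  x[] <- 0
  co <- w$calib$water_coef
  co[] <- 500
  expect_equal(sum(water_use(fake_solution(w, x), co)), 0)
  x["SSA", "maize"] <- 100        # 100 Mt at 500 m3/t = 50 km3
  wu <- water_use(fake_solution(w, x), co)
  expect_equal(unname(wu["SSA"]), 50)
  expect_equal(sum(water_use(fake_solution(w, 2 * x), co)), 2 * sum(wu))
  expect_error(water_use(fake_solution(w, x), co[, 1:3]),
               "accounting error")
})

test_that("emission ledgers are additive over regions and sources", {
  st <- small_ref_run()$steps[["2040"]]
  led <- st$emissions
  by_region <- tapply(led$value, led$region, sum)
  expect_equal(sum(by_region), sum(led$value))
  by_source <- tapply(led$value, led$source, sum)
  expect_equal(sum(by_source), sum(led$value))
})

test_that("non-CO2 emissions respond to substitution in the right direction", {
  ref <- small_ref_run()
  run <- small_level_run(0.5)
  expect_lt(sum(run$steps[["2050"]]$emissions$value),
            sum(ref$steps[["2050"]]$emissions$value))
})
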