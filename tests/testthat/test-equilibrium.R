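test_that("single-market closed forms are recovered", {
  # p = 10 - q, flat marginal cost 4: q* = 6, p* = 4, welfare 18
  sol <- solve_equilibrium(toy_instance())
  expect_equal(unname(sol$consumption[1, 1]), 6, tolerance = 1e-4)
  expect_equal(unname(sol$prices[1, 1]), 4, tolerance = 1e-3)
  expect_equal(sol$welfare, 18, tolerance = 1e-4)
  expect_equal(unname(sol$imports[1, 1]), 0, tolerance = 1e-5)

  # land capped at 4 ha (yield 1): q* = 4, p* = 6, land shadow price 2
  solc <- solve_equilibrium(toy_instance(cropland = 4))
  expect_equal(unname(solc$consumption[1, 1]), 4, tolerance = 1e-4)
  expect_equal(unname(solc$prices[1, 1]), 6, tolerance = 1e-3)
  expect_equal(unname(solc$land_price[1, "cropland"]), 2, tolerance = 1e-3)
})

test_that("the solver matches the brute-force surplus oracle", {
  sol <- solve_equilibrium(two_region_instance())
  oracle <- brute_force_welfare()
  expect_equal(sol$welfare, oracle$welfare,
               tolerance = 1e-3 * abs(oracle$welfare))
  expect_equal(unname(sol$consumption[, 1]), c(oracle$q1, oracle$q2),
               tolerance = 0.02)
  expect_equal(unname(sol$exports["R1", 1]), oracle$t, tolerance = 0.02)
})

test_that("livestock intensity responds to land prices with clamping", {
  resp <- list(eta = 0.2, ref = 100, bounds = c(0.7, 1.15))
  expect_equal(livestock_intensity(100, resp), 1)
  expect_equal(livestock_intensity(50, resp), 0.5^0.2, tolerance = 1e-12)
  expect_equal(0.5^0.2, 0.87055, tolerance = 1e-5)
  expect_equal(livestock_intensity(1e6, resp), 1.15)     # upper clamp
  expect_equal(livestock_intensity(0.01, resp), 0.7)     # lower clamp
  resp0 <- list(eta = 0, ref = 100, bounds = c(0.7, 1.15))
  expect_equal(livestock_intensity(7, resp0), 1)
  expect_error(livestock_intensity(-1, resp), "domain error")
})

test_that("market clearing and land balance hold at every step", {
  for (run in list(small_ref_run(), small_level_run(0.5))) {
    for (st in run$steps) {
      sol <- st$solution
      rel <- abs(sol$clearing_residual) /
        pmax(1, abs(sol$production) + abs(sol$consumption))
      expect_lt(max(rel), 1e-6)
      land <- st$land
      conv <- sol$conversions
      expect_true(all(sol$land_used[, "cropland"] <=
                        land[, "cropland"] + conv[, "n2c"] + conv[, "g2c"] +
                        conv[, "a2c"] + 1e-4))
      expect_true(all(sol$land_used[, "grassland"] <=
                        land[, "grassland"] - conv[, "g2c"] +
                        conv[, "n2g"] + conv[, "a2g"] + 1e-4))
      expect_true(all(st$land_after >= 0))
    }
  }
})

test_that("total area is conserved through the land bookkeeping", {
  for (run in list(small_ref_run(), small_level_run(0.9))) {
    tot0 <- rowSums(run$steps[[1]]$land)
    for (st in run$steps) {
      expect_equal(rowSums(st$land_after), tot0, tolerance = 1e-6)
      # per-step transition record conserves area too: outflows from a class
      # equal the decline of that class plus its inflows
      tr <- st$transitions
      if (nrow(tr) > 0) {
        for (r in unique(tr$region)) {
          d <- tr[tr$region == r, ]
          delta <- st$land_after[r, ] - st$land[r, ]
          for (cl in c("forest", "other_natural")) {
            out <- sum(d$area[d$from == cl]) - sum(d$area[d$to == cl])
            expect_equal(unname(delta[cl]), -out, tolerance = 1e-6)
          }
        }
      }
    }
  }
})

test_that("prices equal inverse demand at consumed quantities", {
  run <- small_ref_run()
  w <- small_world()
  for (st in run$steps) {
    dem <- shift_demand(w, project_drivers(w, st$year))
    p_dem <- dem$a - dem$b * st$solution$consumption
    expect_equal(st$solution$prices, p_dem, tolerance = 1e-4)
  }
})

test_that("the recursive runner enforces its contracts", {
  w <- small_world()
  expect_error(run_scenario(w, scenario_spec(level = .5)),
               "dependency error")
  ref <- small_ref_run()
  expect_length(ref$steps, 4)
  expect_equal(ref$years, seq(2020, 2050, 10))
})

test_that("a zero-level scenario reproduces REF exactly", {
  ref <- small_ref_run()
  run0 <- run_scenario(small_world(), scenario_spec(level = 0), ref = ref)
  for (yr in names(ref$steps)) {
    expect_identical(run0$steps[[yr]]$solution$consumption,
                     ref$steps[[yr]]$solution$consumption)
    expect_identical(run0$steps[[yr]]$solution$prices,
                     ref$steps[[yr]]$solution$prices)
    expect_identical(run0$steps[[yr]]$land_after, ref$steps[[yr]]$land_after)
  }
})

test_that("substitution reduces ruminant production relative to REF", {
  ref <- small_ref_run()
  run <- small_level_run(0.9)
  rum <- c("beef", "milk")
  expect_lt(sum(run$steps[["2050"]]$solution$production[, rum]),
            sum(ref$steps[["2050"]]$solution$production[, rum]))
})

test_that("infeasible instances are reported as such", {
  inst <- toy_instance(cropland = 2)
  inst$fixed_food_demand <- matrix(5, 1, 1,
                                   dimnames = list("R1", "wheat"))
  # demand fixed at 5 but land supports only 2 units and imports have no
  # counterpart region: the wedge cannot be met
  inst$import_caps[] <- 0
  expect_error(solve_equilibrium(inst), "infeasible")
})
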