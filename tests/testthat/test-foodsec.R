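# numerical-integration oracle for the log-normal tail probability
pou_oracle <- function(dec, cv, mder) {
  s2 <- log(1 + cv^2)
  mu <- log(dec) - s2 / 2
  stats::integrate(function(x) stats::dlnorm(x, mu, sqrt(s2)), 0, mder,
                   rel.tol = 1e-10)$value
}

test_that("the log-normal PoU matches numerical integration", {
  expect_equal(prevalence_of_undernourishment(2800, 0.25, 1800)$pou,
               pou_oracle(2800, 0.25, 1800), tolerance = 1e-6)
  expect_equal(pou_oracle(2800, 0.25, 1800), 0.0473, tolerance = 2e-3)
  grid <- expand.grid(dec = c(1900, 2300, 2800, 3400),
                      cv = c(0.2, 0.25, 0.35, 0.5),
                      mder = c(1600, 1800, 2000))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(prevalence_of_undernourishment(g$dec, g$cv, g$mder)$pou,
                 pou_oracle(g$dec, g$cv, g$mder), tolerance = 1e-6)
  }
})

test_that("PoU limits, monotonicity and exclusions hold", {
  expect_lt(prevalence_of_undernourishment(2800, 1e-4, 1800)$pou, 1e-12)
  expect_equal(prevalence_of_undernourishment(2800, 0.25, 1800,
                                              high_income = TRUE)$pou,
               unname(c(0)))
  expect_error(prevalence_of_undernourishment(-1, 0.2, 1800), "domain error")
  expect_error(prevalence_of_undernourishment(2800, 0, 1800), "domain error")
  p0 <- prevalence_of_undernourishment(2500, 0.3, 1800)$pou
  expect_gt(prevalence_of_undernourishment(2400, 0.3, 1800)$pou, p0)
  expect_gt(prevalence_of_undernourishment(2500, 0.35, 1800)$pou, p0)
  expect_gt(prevalence_of_undernourishment(2500, 0.3, 1900)$pou, p0)
  hc <- prevalence_of_undernourishment(2500, 0.3, 1800,
                                       population = 1e8)$headcount
  expect_equal(unname(hc), unname(p0 * 1e8))
})

test_that("the CV projection shrinks the gap with income growth", {
  expect_equal(project_cv(0.35, 1.0), 0.35)             # flat income
  expect_equal(project_cv(0.35, 1.5, rate = 0.02),
               0.2 + 0.15 * 0.9)                        # gap shrinks by 0.10
  expect_equal(project_cv(0.35, 100), 0.2)              # floored
  expect_equal(project_cv(0.35, 0.5), 0.35)             # declines don't worsen
  expect_warning(out <- project_cv(0.1, 1.2), "clamped")
  expect_equal(out, 0.2)
})

test_that("MDER projection is a demographic-weighted mean", {
  g <- c(child = 1600, adult = 2000)
  expect_equal(project_mder(g, c(child = 0.5, adult = 0.5)), 1800)
  expect_equal(project_mder(g, c(child = 0.4, adult = 0.6)), 1840)
  expect_equal(project_mder(c(adult = 1900), c(adult = 1)), 1900)
  shares <- matrix(c(0.5, 0.4, 0.5, 0.6), 2, 2,
                   dimnames = list(c("A", "B"), c("child", "adult")))
  expect_equal(unname(project_mder(g, shares)), c(1800, 1840))
  expect_error(project_mder(g, c(child = 0.5, adult = 0.6)), "domain error")
})

test_that("the Paasche index behaves per its definition", {
  p0 <- c(a = 2, b = 3); p1 <- c(a = 3, b = 3); q1 <- c(a = 1, b = 2)
  expect_equal(paasche_index(p0, p0, q1), 1.0)
  expect_equal(paasche_index(p0, p1, q1), 9 / 8)
  expect_equal(paasche_index(p0, p1, q1 * 17), 9 / 8)   # scale invariance
  # a price change confined to an excluded commodity does not move the index
  p1x <- c(a = 2, b = 30)
  expect_equal(paasche_index(p0, p1x, q1, exclude = "b"), 1.0)
  expect_error(paasche_index(p0, p1, c(a = 0, b = 0)), "domain error")
})

test_that("indicator tables are tidy, complete and additive", {
  tab <- report_indicators(small_ref_run())
  expect_identical(names(tab), c("scenario_id", "year", "region",
                                 "indicator", "unit", "value"))
  expect_identical(unique(tab$scenario_id), "REF")
  expect_true(all(c("pou", "bii", "water", "restored_area",
                    "emissions|total", "price_index|crops",
                    "nitrogen|total_input") %in% tab$indicator))
  # global aggregates: sums for extensive indicators
  for (ind in c("water", "emissions|total", "land|cropland")) {
    sub <- tab[tab$indicator == ind & tab$year == 2050, ]
    expect_equal(sub$value[sub$region == "GLO"],
                 sum(sub$value[sub$region != "GLO"]), tolerance = 1e-8)
  }
  # area-weighted mean for BII
  bii <- tab[tab$indicator == "bii" & tab$year == 2050, ]
  land <- small_ref_run()$steps[["2050"]]$land_after
  wgt <- rowSums(land)
  expect_equal(bii$value[bii$region == "GLO"],
               sum(bii$value[match(names(wgt), bii$region)] * wgt) /
                 sum(wgt), tolerance = 1e-8)
  # runs from different worlds cannot be mixed
  other <- run_scenario(two_region_world())
  expect_error(report_indicators(list(small_ref_run(), other)),
               "consistency error")
})

test_that("dietary energy availability is conserved under substitution", {
  # one-to-one calorie replacement: DEC changes only through the endogenous
  # crop-demand response, not through the swap itself
  ref <- small_ref_run()
  run <- small_level_run(0.5)
  dec_ref <- ref$steps[["2050"]]$food_security$dec
  dec_run <- run$steps[["2050"]]$food_security$dec
  expect_equal(dec_run, dec_ref, tolerance = 0.1)
})
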