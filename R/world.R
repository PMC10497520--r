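# ---- fixed sets -------------------------------------------------------------

#' Macro regions, commodities and land classes
#'
#' Fixed sets used throughout the model: the 13 macro regions, the 18 crop
#' commodities, the 7 animal products, the 6 oil crops and the land classes.
#'
#' @return A character vector of identifiers.
#' @export
fs_regions <- function() {
  c("BRA", "CHN", "FSU", "IND", "MEN", "OAS", "OSA",
    "SEA", "SSA", "ANZ", "CAN", "EUR", "USA")
}

#' @rdname fs_regions
#' @export
fs_crops <- function() {
  c("wheat", "rice", "maize", "barley", "sorghum", "millet",
    "potato", "sweet_potato", "cassava", "sugarcane", "chickpea", "dry_beans",
    "soybean", "rapeseed", "sunflower", "oil_palm", "groundnut", "cottonseed")
}

#' @rdname fs_regions
#' @export
fs_animal_products <- function() {
  c("beef", "pork", "chicken", "milk", "eggs", "other_meat", "other_milk")
}

#' @rdname fs_regions
#' @export
fs_oil_crops <- function() {
  c("soybean", "rapeseed", "sunflower", "oil_palm", "groundnut", "cottonseed")
}

#' @rdname fs_regions
#' @export
fs_land_classes <- function() {
  c("cropland", "grassland", "forest", "other_natural", "abandoned",
    "restored")
}

#' Animal products eligible for substitution by plant-based alternatives
#' @return Character vector: beef, chicken, pork, milk.
#' @export
fs_substitutable <- function() c("beef", "chicken", "pork", "milk")

.fs_commodities <- function() c(fs_crops(), fs_animal_products())

# mean-one log-normal noise
.ln_noise <- function(n, sd) exp(stats::rnorm(n, 0, sd) - sd^2 / 2)

.mat <- function(rows, cols, data = 0) {
  matrix(data, length(rows), length(cols), dimnames = list(rows, cols))
}

# ---- configuration ----------------------------------------------------------

#' World generator configuration
#'
#' Builds (or reads from a YAML file) the configuration of the synthetic world
#' generator: which macro regions to include, the decadal time grid and the
#' amplitude of the log-normal heterogeneity around the archetype parameters.
#'
#' @param regions Character vector of macro-region codes (subset of
#'   \code{fs_regions()}); default all 13.
#' @param years Integer vector, the decadal simulation grid (default
#'   2020--2050).
#' @param noise_sd Standard deviation (log scale) of the regional
#'   perturbations around archetype parameter values.
#' @param file Optional path to a YAML file with fields \code{regions},
#'   \code{years}, \code{noise_sd}; explicit arguments override file values.
#' @return An object of class \code{fs_config}.
#' @export
world_config <- function(regions = fs_regions(), years = seq(2020, 2050, 10),
                         noise_sd = 0.15, file = NULL) {
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.null(y$regions) && missing(regions)) regions <- y$regions
    if (!is.null(y$years) && missing(years)) years <- as.integer(y$years)
    if (!is.null(y$noise_sd) && missing(noise_sd)) noise_sd <- y$noise_sd
  }
  regions <- as.character(regions)
  if (length(regions) < 1 || anyDuplicated(regions) ||
      !all(regions %in% fs_regions())) {
    stop("configuration error: invalid region set; codes must be drawn from ",
         paste(fs_regions(), collapse = ", "))
  }
  years <- as.integer(years)
  if (length(years) < 2 || any(diff(years) != 10)) {
    stop("configuration error: simulation years must form a decadal grid")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("configuration error: noise_sd must be a non-negative number")
  }
  structure(list(regions = regions, years = years, noise_sd = noise_sd),
            class = "fs_config")
}

# ---- regional archetypes ----------------------------------------------------

# Static per-region archetype attributes.  Population in millions (2020),
# income in 1000 USD/person/yr, areas in Mha.  Growth factors are per decade.
.region_archetypes <- function() {
  r <- fs_regions()
  data.frame(
    region = r,
    population = c(213, 1440, 290, 1390, 520, 420, 220, 670, 1140,
                   30, 38, 740, 331),
    pop_growth = c(1.020, 1.007, 1.005, 1.053, 1.060, 1.050, 1.030,
                   1.030, 1.205, 1.040, 1.050, 1.005, 1.040),
    income_pc = c(8.7, 10.0, 10.0, 2.0, 8.0, 4.0, 8.0, 4.5, 1.6,
                  45, 46, 38, 63),
    income_growth = c(1.18, 1.35, 1.20, 1.45, 1.20, 1.30, 1.20,
                      1.35, 1.35, 1.12, 1.12, 1.12, 1.12),
    high_income = r %in% c("ANZ", "CAN", "EUR", "USA"),
    climate_zone = c("tropical", "temperate", "boreal", "tropical",
                     "temperate", "tropical", "tropical", "tropical",
                     "tropical", "temperate", "boreal", "temperate",
                     "temperate"),
    area_total = c(846, 940, 2140, 297, 1200, 800, 900, 430, 2400,
                   800, 910, 560, 920),
    forest_frac = c(0.70, 0.30, 0.55, 0.30, 0.05, 0.35, 0.45, 0.70,
                    0.30, 0.20, 0.60, 0.45, 0.40),
    forest_biome_share = c(0.75, 0.45, 0.60, 0.40, 0.10, 0.50, 0.55,
                           0.80, 0.35, 0.25, 0.65, 0.60, 0.45),
    stringsAsFactors = FALSE
  )
}

# Global commodity archetypes: producer price (USD/t), calorie content
# (kcal/kg), per-capita availability at reference income (kcal/person/day),
# income and price elasticities of demand.
.commodity_archetypes <- function() {
  cc <- .fs_commodities()
  a <- data.frame(
    commodity = cc,
    price = c(220, 380, 190, 180, 200, 250, 250, 280, 150, 40, 600, 650,
              420, 450, 480, 140, 900, 250,
              4000, 2200, 1700, 450, 1500, 3500, 500),
    kcal_per_kg = c(3340, 3600, 3560, 3300, 3290, 3400, 770, 860, 1600, 300,
                    3640, 3410, 4000, 4900, 5000, 2000, 5670, 4100,
                    2500, 2400, 1450, 610, 1400, 2300, 700),
    kcal_pc = c(480, 530, 140, 30, 40, 30, 60, 25, 50, 190, 25, 40,
                90, 60, 45, 120, 40, 10,
                60, 110, 90, 135, 35, 20, 15),
    income_elast = c(0.15, 0.10, 0.05, 0.05, 0.02, 0.02, 0.10, 0.02, 0.02,
                     0.20, 0.20, 0.10, 0.30, 0.30, 0.30, 0.35, 0.25, 0.10,
                     0.30, 0.28, 0.37, 0.32, 0.30, 0.25, 0.25),
    price_elast = c(rep(0.30, 12), rep(0.40, 6), rep(0.50, 7)),
    stringsAsFactors = FALSE
  )
  rownames(a) <- cc
  a
}

# Global livestock archetypes: feed conversion (t feed/t product), grassland
# requirement (ha/t, ruminants only) and emission/nitrogen coefficients.
.livestock_archetypes <- function() {
  ap <- fs_animal_products()
  data.frame(
    product = ap,
    feed_conv = c(2.5, 3.0, 2.2, 0.30, 2.3, 0.8, 0.20),
    grass_req = c(20, 0, 0, 0.70, 0, 25, 1.5),
    enteric_ch4 = c(0.30, 0.012, 0.001, 0.021, 0.001, 0.25, 0.030),
    manure_ch4 = c(0.020, 0.030, 0.002, 0.005, 0.002, 0.010, 0.004),
    n_excretion = c(0.30, 0.030, 0.020, 0.008, 0.020, 0.25, 0.010),
    pasture_share = c(0.60, 0.05, 0.05, 0.50, 0.05, 0.70, 0.50),
    row.names = ap, stringsAsFactors = FALSE
  )
}

.crop_archetypes <- function() {
  cr <- fs_crops()
  data.frame(
    crop = cr,
    yield = c(3.5, 4.5, 5.5, 3.0, 1.5, 1.0, 20, 13, 12, 70, 1.1, 1.0,
              2.8, 2.0, 2.0, 15, 1.7, 2.2),
    harvested_n = c(0.020, 0.012, 0.014, 0.016, 0.014, 0.014, 0.003, 0.003,
                    0.002, 0.002, 0.030, 0.032, 0.060, 0.033, 0.028, 0.003,
                    0.035, 0.025),
    water_coef = c(1000, 1500, 800, 700, 600, 500, 250, 250, 300, 150, 700,
                   700, 1500, 900, 900, 400, 1100, 900),
    feed_share = c(0.12, 0, 0.40, 0.10, 0.06, 0, 0, 0, 0.07, 0, 0, 0,
                   0.25, 0, 0, 0, 0, 0),
    row.names = cr, stringsAsFactors = FALSE
  )
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic world baseline
#'
#' Deterministic, seeded generator of a synthetic world with the structure the
#' scenario analysis assumes: macro regions with SSP2-like monotone population
#' and income trajectories, 18 crops and 7 animal products with linear inverse
#' demand and linear marginal cost curves, land endowments by class, livestock
#' feed-conversion and emission coefficients, nutrient/amino-acid fixtures for
#' the recipe ingredients, and a base-year (2020) market equilibrium solved so
#' that all markets clear exactly.
#'
#' Identical \code{(config, seed)} pairs give bit-identical worlds.
#'
#' @param config An \code{fs_config} from \code{\link{world_config}}.
#' @param seed Integer RNG seed.
#' @return An object of class \code{fs_world}: a list with elements
#'   \code{config}, \code{regions} (data frame of regional attributes),
#'   \code{commodities}, \code{drivers} (population and income trajectories),
#'   \code{nutrients}, \code{calib} (all model coefficients as named
#'   scalars/vectors/matrices) and \code{base_state} (solved 2020 state).
#' @examples
#' w <- generate_world(world_config(regions = c("BRA", "EUR")), seed = 1)
#' summary(w)
#' @export
generate_world <- function(config = world_config(), seed = 1L) {
  if (!inherits(config, "fs_config")) config <- do.call(world_config, config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  regs <- config$regions
  R <- length(regs)
  crops <- fs_crops(); animals <- fs_animal_products()
  cc <- .fs_commodities()
  sdl <- config$noise_sd

  ra <- .region_archetypes()
  ra <- ra[match(regs, ra$region), , drop = FALSE]
  rownames(ra) <- regs
  ca <- .commodity_archetypes()
  la <- .livestock_archetypes()
  cra <- .crop_archetypes()

  years <- config$years
  Tn <- length(years)
  dec <- (years - years[1]) / 10

  # drivers: monotone population and income paths with decelerating growth
  # rates (SSP2-like convergence), slight noise on the base growth rate
  pgrow <- ra$pop_growth * .ln_noise(R, sdl / 10)
  igrow <- ra$income_growth * .ln_noise(R, sdl / 10)
  pgrow <- pmax(pgrow, 1.001)   # generator contract: strictly growing
  igrow <- pmax(igrow, 1.001)
  pop <- matrix(ra$population, R, Tn)
  inc <- matrix(ra$income_pc, R, Tn)
  if (Tn > 1) for (k in 2:Tn) {
    pop[, k] <- pop[, k - 1] * (1 + (pgrow - 1) * 0.90^(k - 2))
    inc[, k] <- inc[, k - 1] * (1 + (igrow - 1) * 0.85^(k - 2))
  }
  dimnames(pop) <- dimnames(inc) <- list(regs, years)

  # base-year diet: dietary energy availability scaled by income, split into
  # an ASF share (rising with income) and crops
  inc0 <- inc[, 1]
  dec_kcal <- 3400 - 1300 * exp(-inc0 / 11)
  asf_share <- 0.12 + 0.18 * (1 - exp(-inc0 / 20))
  arch_kcal <- ca$kcal_pc
  names(arch_kcal) <- cc
  is_crop <- cc %in% crops
  mix_noise <- .mat(regs, cc, .ln_noise(R * length(cc), 2 * sdl))
  kcal_r <- t(t(mix_noise) * arch_kcal)
  crop_k <- kcal_r[, is_crop, drop = FALSE]
  anim_k <- kcal_r[, !is_crop, drop = FALSE]
  crop_k <- crop_k / rowSums(crop_k) * (dec_kcal * (1 - asf_share))
  anim_k <- anim_k / rowSums(anim_k) * (dec_kcal * asf_share)
  kcal_r <- cbind(crop_k, anim_k)[, cc, drop = FALSE]

  # regional calorie content (kcal/kg), small variation
  calorie <- t(t(.mat(regs, cc, .ln_noise(R * length(cc), 0.03))) *
                 ca$kcal_per_kg)

  # base-year food demand in Mt: kcal/day -> kg/yr -> Mt
  q0 <- kcal_r * 365 / calorie          # kg/person/yr
  q0 <- q0 * pop[, 1] / 1000            # Mt (pop in millions)
  q0 <- pmax(q0, 0.005)

  # livestock production shares and feed demand
  x0a <- q0[, animals, drop = FALSE] * .mat(regs, animals,
                                            .ln_noise(R * 7, 1.5 * sdl))
  x0a <- t(t(x0a) * colSums(q0[, animals, drop = FALSE]) / colSums(x0a))

  feed_conv <- t(t(.mat(regs, animals, .ln_noise(R * 7, sdl))) * la$feed_conv)
  feed_share_mat <- .mat(crops, animals, 0)
  for (a in animals) feed_share_mat[, a] <- cra$feed_share
  feed0 <- feed_share_mat %*% t(feed_conv * x0a)   # crops x regions
  feed0 <- t(feed0)                                # regions x crops

  # crop production: total demand distributed with heterogeneity, balanced
  d0c <- q0[, crops, drop = FALSE] + feed0
  x0c <- d0c * .mat(regs, crops, .ln_noise(R * 18, 1.5 * sdl))
  x0c <- t(t(x0c) * colSums(d0c) / colSums(x0c))
  x0 <- cbind(x0c, x0a)[, cc, drop = FALSE]
  x0 <- pmax(x0, 0.005)

  # yields (t/ha) with income-linked productivity
  prodmult <- (inc0 / 11)^0.15 * .ln_noise(R, sdl)
  yield <- outer(prodmult, cra$yield)
  dimnames(yield) <- list(regs, crops)

  # grassland requirement (ha/t): more extensive where productivity is low;
  # rescaled below if the region's land cannot accommodate it
  grass_req <- t(t(.mat(regs, animals, 1 / pmin(pmax(prodmult, 0.5), 2.0))) *
                   la$grass_req)

  cropland0 <- rowSums(x0c / yield)
  # land-constrained regions run more productive systems so the base-year
  # footprint fits inside the region: crops first, then ruminants
  yfit <- pmax(1, cropland0 / (0.80 * ra$area_total))
  yield <- yield * yfit
  cropland0 <- cropland0 / yfit
  grassland0 <- rowSums(grass_req * x0a)
  gfit <- pmin(1, pmax(0.85 * ra$area_total - cropland0,
                       0.02 * ra$area_total) / pmax(grassland0, 1e-9))
  grass_req <- grass_req * gfit
  grassland0 <- grassland0 * gfit
  cropland_end <- cropland0 * 1.02
  grassland_end <- grassland0 * 1.03
  remain <- pmax(ra$area_total - cropland_end - grassland_end, 1)
  forest0 <- remain * ra$forest_frac
  other0 <- remain * (1 - ra$forest_frac)

  # demand curves p = a - b q calibrated at (p0, q0); price in USD/t, q in Mt
  p0 <- t(t(.mat(regs, cc, .ln_noise(R * length(cc), sdl / 2))) * ca$price)
  eps_d <- ca$price_elast
  b0 <- t(t(p0 / q0) / eps_d)
  a0 <- p0 + b0 * q0

  # supply marginal cost c + d x, elasticity 1.2 at the calibration point
  eps_s <- 1.2
  d0 <- p0 / (eps_s * x0)
  c0 <- p0 - d0 * x0                  # = p0 (1 - 1/eps_s) >= 0

  # trade costs per tonne (export + import legs)
  tc_exp <- t(t(.mat(regs, cc, .ln_noise(R * length(cc), sdl))) *
                (0.04 * ca$price + 10))
  tc_imp <- tc_exp * .ln_noise(R * length(cc), sdl / 2)

  calib <- list(
    demand_a = a0, demand_b = b0,
    income_elast = stats::setNames(ca$income_elast, cc),
    supply_c = c0, supply_d = d0,
    capacity_growth = stats::setNames(pgrow * 1.05, regs),
    tech_decline = 0.97,
    yield = yield, yield_growth = 1.06,
    livestock_productivity_growth = 1.08,
    feed_conv = feed_conv, feed_share = feed_share_mat,
    grass_req = grass_req,
    trade_cost_exp = tc_exp, trade_cost_imp = tc_imp, trade_quad = 0.5,
    # annualized land-conversion costs (USD/ha/yr equivalent); reuse of
    # abandoned agricultural land is much cheaper than clearing natural land
    conv_cost = .mat(regs, c("n2c", "n2g", "g2c", "a2c", "a2g"),
                     rep(c(70, 35, 20, 10, 5), each = R)),
    conv_quad = 0.5,
    calorie = calorie,
    water_coef = cbind(
      t(t(.mat(regs, crops, .ln_noise(R * 18, sdl))) * cra$water_coef),
      t(t(.mat(regs, animals, .ln_noise(R * 7, sdl))) *
          c(1500, 400, 300, 100, 300, 1200, 150))),
    ef_enteric = t(t(.mat(regs, animals, 1 / pmin(pmax(prodmult, 0.6), 1.6))) *
                     la$enteric_ch4),
    ef_manure_ch4 = t(t(.mat(regs, animals, .ln_noise(R * 7, sdl))) *
                        la$manure_ch4),
    ef_rice_ch4 = stats::setNames(0.15 * .ln_noise(R, sdl), regs),
    ef_n2o_soil = 0.0157, ef_n2o_pasture = 0.0314,
    gwp_ch4 = 28, gwp_n2o = 265,
    carbon_stock = {
      zs <- ra$climate_zone
      cs <- .mat(regs, fs_land_classes(), 0)
      cs[, "forest"] <- c(tropical = 150, temperate = 100, boreal = 80)[zs]
      cs[, "other_natural"] <- 40
      cs[, "grassland"] <- 10
      cs[, "cropland"] <- 5
      cs[, "abandoned"] <- 10
      cs[, "restored"] <- cs[, "forest"]
      cs
    },
    n_harvest = t(t(.mat(regs, crops, .ln_noise(R * 18, sdl / 2))) *
                    cra$harvested_n),
    n_nue = .mat(regs, crops, pmin(pmax(0.5 * .ln_noise(R * 18, sdl), 0.3),
                                   0.8)),
    n_excretion = t(t(.mat(regs, animals, .ln_noise(R * 7, sdl))) *
                      la$n_excretion),
    n_mm_eff = .mat(regs, animals, pmin(pmax(0.4 * .ln_noise(R * 7, sdl),
                                             0.2), 0.7)),
    n_pasture_share = t(t(.mat(regs, animals, 1)) * la$pasture_share),
    lr_eta = 0.2, lr_bounds = c(0.7, 1.15), lr_rent_floor = 100,
    # regrowth saturates at the mature-forest carbon density of the zone;
    # rate anchored on secondary-forest chronosequences (tropical stands
    # recover ~40% of mature density after 20 yr)
    rest_cmax = c(tropical = 150, temperate = 100, boreal = 80),
    rest_k = c(tropical = 0.026, temperate = 0.020, boreal = 0.012),
    bii_coef = c(cropland = 0.40, grassland = 0.55, forest = 0.95,
                 other_natural = 0.70, abandoned = 0.70, restored = 0.70,
                 primary = 1.0),
    bii_recovery_ceiling = 0.95, bii_recovery_years = 60,
    rest_min = stats::setNames(rep(0, R), regs),
    rest_max = stats::setNames(rep(Inf, R), regs),
    cv0 = stats::setNames(pmax(0.2 + 0.25 * exp(-inc0 / 8), 0.2), regs),
    cv_rate = 0.02, cv_floor = 0.2,
    mder_groups = c(child = 1300, adult = 1950, elderly = 1750),
    mder_share_child = .mder_shares(regs, inc0, years, "child"),
    mder_share_adult = .mder_shares(regs, inc0, years, "adult"),
    mder_share_elderly = .mder_shares(regs, inc0, years, "elderly")
  )

  regions <- data.frame(
    region = regs,
    high_income = ra$high_income,
    climate_zone = ra$climate_zone,
    forest_biome_share = ra$forest_biome_share,
    area_total = ra$area_total,
    cropland = cropland_end, grassland = grassland_end,
    forest = forest0, other_natural = other0,
    row.names = regs, stringsAsFactors = FALSE
  )

  world <- structure(list(
    config = config,
    seed = as.integer(seed),
    regions = regions,
    commodities = list(crops = crops, animal_products = animals,
                       oil_crops = fs_oil_crops(),
                       calorie_content = calorie),
    drivers = list(years = years, population = pop, income_pc = inc),
    nutrients = default_nutrients(),
    conversions = default_conversions(),
    calib = calib,
    base_state = NULL
  ), class = "fs_world")

  # base-year equilibrium: the generated 2020 state clears all markets.
  # The agricultural endowments are then tightened to the solved land use
  # (the land constraints are slack at the calibration point, so the
  # equilibrium is unchanged and the base year starts without spurious
  # abandonment).
  inst <- build_market_instance(world, year = years[1])
  sol <- solve_equilibrium(inst)
  world$regions$cropland <- sol$land_used[, "cropland"]
  world$regions$grassland <- sol$land_used[, "grassland"]
  world$base_state <- .make_state(world, years[1], sol,
                                  land = .initial_land(world))
  world$calib$lr_ref_price <- world$calib$lr_rent_floor +
    sol$land_price[, "grassland"]
  world
}

# demographic group shares, aging slowly over time
.mder_shares <- function(regs, inc0, years, group) {
  k <- (years - years[1]) / 10
  child0 <- 0.16 + 0.26 * exp(-inc0 / 6)
  old0 <- 0.06 + 0.12 * (1 - exp(-inc0 / 15))
  child <- outer(child0, 0.93^k)
  old <- outer(old0, 1.10^k)
  adult <- 1 - child - old
  m <- switch(group, child = child, adult = adult, elderly = old)
  dimnames(m) <- list(regs, years)
  m
}

.initial_land <- function(world) {
  regs <- world$config$regions
  land <- .mat(regs, fs_land_classes(), 0)
  land[, "cropland"] <- world$regions$cropland
  land[, "grassland"] <- world$regions$grassland
  land[, "forest"] <- world$regions$forest
  land[, "other_natural"] <- world$regions$other_natural
  land
}

.make_state <- function(world, year, sol, land) {
  structure(list(year = year, land = land, solution = sol), class = "fs_state")
}

# ---- drivers and demand shifting -------------------------------------------

#' Exogenous demographic and income drivers at a given year
#'
#' Drivers are fully exogenous: they are identical across all scenarios run on
#' the same world.
#'
#' @param world An \code{fs_world}.
#' @param year A year on the simulation grid.
#' @return List with named vectors \code{population} (millions) and
#'   \code{income_pc} (1000 USD/person/yr).
#' @export
project_drivers <- function(world, year) {
  yrs <- world$drivers$years
  if (!year %in% yrs) {
    stop("range error: year ", year, " is outside the simulation grid (",
         paste(range(yrs), collapse = "-"), ")")
  }
  j <- match(year, yrs)
  list(year = year,
       population = world$drivers$population[, j],
       income_pc = world$drivers$income_pc[, j])
}

#' Shift demand curves with population and income growth
#'
#' Quantity demanded at any fixed price scales with population and with income
#' per capita raised to the commodity's income elasticity; the inverse-demand
#' price intercept is preserved and the slope is rescaled so the per-capita
#' price response is unchanged.
#'
#' @param calibration The world's \code{calib} list (or an \code{fs_world},
#'   from which it is taken).
#' @param drivers A driver set from \code{\link{project_drivers}}, or a list
#'   with \code{pop_ratio} and \code{income_ratio} named vectors (per region)
#'   relative to the base year.
#' @param base Optional base-year drivers (defaults to the world's base year
#'   when an \code{fs_world} is given).
#' @return List with matrices \code{a} and \code{b} (inverse demand
#'   \eqn{p = a - b q}) and the demand multiplier matrix \code{m}.
#' @export
shift_demand <- function(calibration, drivers, base = NULL) {
  if (inherits(calibration, "fs_world")) {
    world <- calibration
    calibration <- world$calib
    if (is.null(base)) base <- project_drivers(world, world$drivers$years[1])
  }
  if (!is.null(drivers$pop_ratio)) {
    pr <- drivers$pop_ratio; ir <- drivers$income_ratio
  } else {
    if (is.null(base)) stop("configuration error: base-year drivers required")
    pr <- drivers$population / base$population
    ir <- drivers$income_pc / base$income_pc
  }
  eta <- calibration$income_elast
  if (is.null(eta) || any(is.na(eta))) {
    stop("configuration error: missing income elasticity")
  }
  m <- outer(pr, rep(1, length(eta))) * outer(ir, eta, "^")
  dimnames(m) <- dimnames(calibration$demand_a)
  list(a = calibration$demand_a, b = calibration$demand_b / m, m = m)
}

# supply-side parameters at a given year: technical progress lowers costs and
# capacity grows with demand so the capacity-scaled slope stays comparable
.shift_supply <- function(world, year) {
  k <- (year - world$drivers$years[1]) / 10
  cg <- world$calib$capacity_growth^k
  td <- world$calib$tech_decline^k
  list(c = world$calib$supply_c * td,
       d = world$calib$supply_d * td / cg,
       yield = world$calib$yield * world$calib$yield_growth^k)
}
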