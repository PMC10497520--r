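# ---- market instance --------------------------------------------------------

#' Build a one-step market instance
#'
#' Assembles the quadratic-program data for a single time step: linear inverse
#' demand per (region, commodity), linear marginal cost supply, net trade
#' through a world pool with per-unit export/import costs, land balances with
#' one-way conversion of natural land to agriculture (plus grassland-to-
#' cropland conversion), derived feed demand, and the scenario constraint
#' blocks (exogenous substitution wedges, alternative-ingredient crop demand,
#' import caps).
#'
#' @param world An \code{fs_world}.
#' @param year Year on the simulation grid.
#' @param demand Optional demand parameters (list \code{a}, \code{b}) from
#'   \code{\link{shift_demand}}; computed from the world drivers when omitted.
#' @param land Optional land endowment matrix (regions x land classes);
#'   defaults to the world's base-year endowments.
#' @param intensity Optional named vector of ruminant intensity multipliers
#'   per region (from \code{\link{livestock_intensity}}); default 1.
#' @param fixed_food_demand Optional matrix (regions x commodities) with
#'   non-NA entries fixing food demand exogenously (the substitution wedge).
#' @param alt_crop_demand Optional matrix (regions x crops) of exogenous
#'   primary-crop demand for novel-alternative production.
#' @param import_caps Optional matrix (regions x crops) of upper bounds on
#'   imports across the macro-region border; \code{Inf} = uncapped.
#' @return An object of class \code{fs_instance}.
#' @export
build_market_instance <- function(world, year,
                                  demand = NULL, land = NULL,
                                  intensity = NULL,
                                  fixed_food_demand = NULL,
                                  alt_crop_demand = NULL,
                                  import_caps = NULL) {
  regs <- world$config$regions
  crops <- world$commodities$crops
  animals <- world$commodities$animal_products
  cc <- c(crops, animals)
  R <- length(regs); C <- length(cc)

  if (is.null(demand)) {
    demand <- shift_demand(world, project_drivers(world, year))
  }
  sup <- .shift_supply(world, year)
  if (is.null(land)) land <- .initial_land(world)
  land <- pmax(land, 0)
  if (is.null(intensity)) {
    intensity <- stats::setNames(rep(1, R), regs)
  }
  ruminant <- world$calib$grass_req[1, ] > 0
  k <- (year - world$drivers$years[1]) / 10
  lpg <- world$calib$livestock_productivity_growth^k
  grass_req <- sweep(world$calib$grass_req, 1, intensity * lpg, "/")
  grass_req[, !ruminant] <- 0

  if (is.null(alt_crop_demand)) alt_crop_demand <- .mat(regs, crops, 0)
  if (is.null(import_caps)) import_caps <- .mat(regs, crops, Inf)

  if (!all(is.finite(demand$a)) || !all(is.finite(demand$b)) ||
      any(demand$b <= 0) || any(sup$d < 0)) {
    stop("parameter error: demand/supply coefficients must be finite with ",
         "negative demand slopes and non-negative supply slopes")
  }

  structure(list(
    year = year, regions = regs, commodities = cc,
    crops = crops, animals = animals,
    demand_a = demand$a, demand_b = demand$b,
    supply_c = sup$c, supply_d = sup$d,
    yield = sup$yield, grass_req = grass_req,
    feed_conv = world$calib$feed_conv, feed_share = world$calib$feed_share,
    trade_cost_exp = world$calib$trade_cost_exp,
    trade_cost_imp = world$calib$trade_cost_imp,
    trade_quad = world$calib$trade_quad,
    conv_cost = world$calib$conv_cost, conv_quad = world$calib$conv_quad,
    land = land,
    fixed_food_demand = fixed_food_demand,
    alt_crop_demand = alt_crop_demand,
    import_caps = import_caps
  ), class = "fs_instance")
}

# ---- solver -----------------------------------------------------------------

#' Solve a market equilibrium
#'
#' Maximizes the sum of consumer and producer surpluses (area under the
#' inverse demand curves minus production, trade and land-conversion costs)
#' subject to market clearing, land balances and scenario constraints.  With
#' linear demand and supply this is a strictly concave quadratic program,
#' solved with the Goldfarb-Idnani dual active-set method.  Market prices are
#' the duals of the clearing constraints; for commodities with endogenous
#' demand they coincide with the inverse demand evaluated at consumed
#' quantities.
#'
#' @param instance An \code{fs_instance} from
#'   \code{\link{build_market_instance}}.
#' @return An object of class \code{fs_equilibrium} with consumption,
#'   production, trade, land use and conversions, prices, land shadow prices
#'   and the welfare objective value.  Quantities are Mt, areas Mha, prices
#'   USD/t, land shadow prices USD/ha, welfare million USD.
#' @examples
#' w <- generate_world(world_config(regions = c("BRA", "EUR")), seed = 1)
#' eq <- solve_equilibrium(build_market_instance(w, 2020))
#' eq$prices[, "wheat"]
#' @export
solve_equilibrium <- function(instance) {
  inst <- instance
  regs <- inst$regions; cc <- inst$commodities
  crops <- inst$crops; animals <- inst$animals
  R <- length(regs); C <- length(cc)
  nRC <- R * C
  # variable layout: q | x | m | e | conv (n2c | n2g | g2c | a2c | a2g)
  off_x <- nRC; off_m <- 2L * nRC; off_e <- 3L * nRC; off_cv <- 4L * nRC
  nconv <- 5L
  n <- 4L * nRC + nconv * R

  Dd <- c(as.vector(inst$demand_b), as.vector(inst$supply_d),
          rep(inst$trade_quad, 2L * nRC),
          rep(inst$conv_quad, nconv * R))
  Dd <- pmax(Dd, 1e-6)    # strict convexity floor; far below model scale
  dv <- c(as.vector(inst$demand_a), -as.vector(inst$supply_c),
          -as.vector(inst$trade_cost_imp), -as.vector(inst$trade_cost_exp),
          -as.vector(inst$conv_cost))

  ## equality block 1: clearing per (region, commodity)
  ##   x + m - e - q - feed_use(x_animals) = alt_demand
  n_eq_extra <- 0L
  fixed <- inst$fixed_food_demand
  if (!is.null(fixed)) n_eq_extra <- sum(!is.na(fixed))
  caps <- inst$import_caps
  cap_idx <- which(is.finite(caps), arr.ind = TRUE)
  m_ineq <- 5L * R + nrow(cap_idx) + n
  m_all <- nRC + C + n_eq_extra + m_ineq
  A <- matrix(0, n, m_all)
  b0 <- numeric(m_all)

  col <- 0L
  feed_mat <- inst$feed_share   # crops x animals
  for (ci in seq_len(C)) for (ri in seq_len(R)) {
    col <- col + 1L
    k <- (ci - 1L) * R + ri
    A[k, col] <- -1                     # -q
    A[off_x + k, col] <- 1              # +x
    A[off_m + k, col] <- 1              # +m
    A[off_e + k, col] <- -1             # -e
    cname <- cc[ci]
    if (cname %in% crops) {
      fsh <- feed_mat[cname, ]
      act <- which(fsh > 0)
      for (a in act) {
        ai <- match(animals[a], cc)
        A[off_x + (ai - 1L) * R + ri, col] <-
          A[off_x + (ai - 1L) * R + ri, col] -
          fsh[a] * inst$feed_conv[ri, a]
      }
      b0[col] <- inst$alt_crop_demand[ri, cname]
    } else {
      b0[col] <- 0
    }
  }
  ## equality block 2: world pool balance per commodity
  for (ci in seq_len(C)) {
    col <- col + 1L
    k <- ((ci - 1L) * R + 1L):(ci * R)
    A[off_m + k, col] <- 1
    A[off_e + k, col] <- -1
    b0[col] <- 0
  }
  ## equality block 3: exogenous (substitution) food demand
  if (n_eq_extra > 0L) {
    fx <- which(!is.na(fixed), arr.ind = TRUE)
    for (j in seq_len(nrow(fx))) {
      col <- col + 1L
      k <- (match(colnames(fixed)[fx[j, 2]], cc) - 1L) * R + fx[j, 1]
      A[k, col] <- 1
      b0[col] <- fixed[fx[j, 1], fx[j, 2]]
    }
  }
  meq <- col

  ## inequalities (A'z >= b0)
  inv_yield <- 1 / inst$yield
  row_crop_start <- col + 1L
  for (ri in seq_len(R)) {            # cropland balance
    col <- col + 1L
    for (cr in crops) {
      A[off_x + (match(cr, cc) - 1L) * R + ri, col] <- -inv_yield[ri, cr]
    }
    A[off_cv + ri, col] <- 1              # n2c
    A[off_cv + 2L * R + ri, col] <- 1     # g2c
    A[off_cv + 3L * R + ri, col] <- 1     # a2c
    b0[col] <- -inst$land[ri, "cropland"]
  }
  row_grass_start <- col + 1L
  for (ri in seq_len(R)) {            # grassland balance
    col <- col + 1L
    for (a in seq_along(animals)) {
      gr <- inst$grass_req[ri, a]
      if (gr > 0) A[off_x + (match(animals[a], cc) - 1L) * R + ri, col] <- -gr
    }
    A[off_cv + R + ri, col] <- 1          # n2g adds grassland
    A[off_cv + 2L * R + ri, col] <- -1    # g2c removes grassland
    A[off_cv + 4L * R + ri, col] <- 1     # a2g
    b0[col] <- -inst$land[ri, "grassland"]
  }
  for (ri in seq_len(R)) {            # natural land available for conversion
    col <- col + 1L
    A[off_cv + ri, col] <- -1
    A[off_cv + R + ri, col] <- -1
    b0[col] <- -(inst$land[ri, "forest"] + inst$land[ri, "other_natural"])
  }
  for (ri in seq_len(R)) {            # g2c cannot exceed grassland endowment
    col <- col + 1L
    A[off_cv + 2L * R + ri, col] <- -1
    b0[col] <- -inst$land[ri, "grassland"]
  }
  for (ri in seq_len(R)) {            # abandoned-land reuse limited by pool
    col <- col + 1L
    A[off_cv + 3L * R + ri, col] <- -1
    A[off_cv + 4L * R + ri, col] <- -1
    b0[col] <- -inst$land[ri, "abandoned"]
  }
  if (nrow(cap_idx) > 0L) {           # import caps (crops)
    for (j in seq_len(nrow(cap_idx))) {
      col <- col + 1L
      ri <- cap_idx[j, 1]; cr <- colnames(caps)[cap_idx[j, 2]]
      A[off_m + (match(cr, cc) - 1L) * R + ri, col] <- -1
      b0[col] <- -caps[cap_idx[j, 1], cap_idx[j, 2]]
    }
  }
  nn_start <- col + 1L
  for (j in seq_len(n)) {             # non-negativity
    col <- col + 1L
    A[j, col] <- 1
    b0[col] <- 0
  }

  # tiny slack on the inequality rows guards the dual active-set method
  # against degenerate vertices (several resources exactly exhausted);
  # equalities stay exact.  Escalate the slack once before giving up.
  solve_once <- function(slack) {
    b <- b0
    b[(meq + 1L):m_all] <- b[(meq + 1L):m_all] - slack
    quadprog::solve.QP(Dmat = diag(Dd), dvec = dv, Amat = A, bvec = b,
                       meq = meq)
  }
  sol <- tryCatch(
    solve_once(5e-7),
    error = function(e1) tryCatch(
      solve_once(1e-4),
      error = function(e) {
        stop("infeasible constraint set at year ", inst$year, ": ",
             conditionMessage(e),
             if (nrow(cap_idx) > 0L) {
               " (import caps and exogenous demand wedges are the usual binding blocks)"
             } else "", call. = FALSE)
      }))
  z <- pmax(sol$solution, 0)   # all variables are non-negative by model
  z[z < 1e-9] <- 0
  welfare <- sum(dv * z) - 0.5 * sum(Dd * z^2)

  grab <- function(off) {
    m <- matrix(z[(off + 1L):(off + nRC)], R, C, dimnames = list(regs, cc))
    m
  }
  q <- grab(0L); x <- grab(off_x); imp <- grab(off_m); exp_ <- grab(off_e)
  conv <- matrix(z[(off_cv + 1L):(off_cv + nconv * R)], R, nconv,
                 dimnames = list(regs, c("n2c", "n2g", "g2c", "a2c", "a2g")))

  feed_use <- .mat(regs, crops, 0)
  xa <- x[, animals, drop = FALSE]
  for (cr in crops) {
    fsh <- feed_mat[cr, ]
    if (any(fsh > 0)) {
      feed_use[, cr] <- rowSums(sweep(xa * inst$feed_conv, 2, fsh, "*"))
    }
  }

  lag <- sol$Lagrangian
  # clearing duals: price of relaxing one unit of exogenous demand
  price <- matrix(lag[seq_len(nRC)], R, C, dimnames = list(regs, cc))
  land_price <- cbind(
    cropland = lag[row_crop_start:(row_crop_start + R - 1L)],
    grassland = lag[row_grass_start:(row_grass_start + R - 1L)])
  rownames(land_price) <- regs

  land_used <- cbind(
    cropland = rowSums(x[, crops, drop = FALSE] * inv_yield),
    grassland = rowSums(x[, animals, drop = FALSE] * inst$grass_req))
  rownames(land_used) <- regs

  clearing <- x + imp - exp_ - q -
    cbind(feed_use, .mat(regs, animals, 0))[, cc, drop = FALSE] -
    cbind(inst$alt_crop_demand, .mat(regs, animals, 0))[, cc, drop = FALSE]

  structure(list(
    year = inst$year,
    consumption = q, production = x,
    imports = imp, exports = exp_,
    feed_use = feed_use,
    alt_ingredient_use = inst$alt_crop_demand,
    conversions = conv,
    prices = price,
    land_price = land_price,
    land_used = land_used,
    welfare = welfare,
    clearing_residual = clearing,
    iterations = sol$iterations
  ), class = "fs_equilibrium")
}

# ---- livestock extensification ---------------------------------------------

#' Ruminant intensity response to land prices
#'
#' Cheap land encourages extensification: the intensity multiplier
#' \eqn{\phi = \mathrm{clamp}((P_L/P_{ref})^\eta)} scales ruminant
#' productivity, so lower land prices raise per-unit grassland use and
#' enteric emission intensity (both divided by \eqn{\phi}).
#'
#' @param land_price Land price(s), USD/ha (non-negative).
#' @param response List with \code{eta} (elasticity, >= 0), \code{ref}
#'   (reference land price) and \code{bounds} (length-2 clamp).
#' @return Intensity multiplier(s) in \code{bounds}; 1 at the reference price.
#' @export
livestock_intensity <- function(land_price, response) {
  if (any(land_price < 0)) stop("domain error: negative land price")
  eta <- response$eta
  if (eta < 0) stop("domain error: eta must be non-negative")
  phi <- (land_price / response$ref)^eta
  pmin(pmax(phi, response$bounds[1]), response$bounds[2])
}

# ---- recursive runner -------------------------------------------------------

#' Run a scenario trajectory (recursive-dynamic)
#'
#' Solves the market equilibrium in 10-year steps over the simulation grid.
#' Each step consumes the previous step's land state: land in use becomes the
#' next step's endowment, conversions draw down natural land, and abandoned
#' agricultural area accumulates in a pool that feeds the restoration
#' accounts.  Scenario runs take the substitution percentages, import caps
#' and alternative-ingredient demand from the REF trajectory, which must be
#' supplied.
#'
#' @param world An \code{fs_world}.
#' @param scenario A \code{fs_scenario} from \code{\link{scenario_spec}}, or
#'   \code{NULL} for the reference (REF) run.
#' @param ref A completed REF \code{fs_run} (required when \code{scenario} is
#'   not \code{NULL}).
#' @return An object of class \code{fs_run}: per-step states, equilibrium
#'   solutions, emission/nitrogen/water accounts, restoration ledger, BII and
#'   food-security metrics.
#' @examples
#' w <- generate_world(world_config(regions = c("BRA", "EUR")), seed = 1)
#' ref <- run_scenario(w)
#' sc <- scenario_spec(level = 0.5)
#' run <- run_scenario(w, sc, ref = ref)
#' summary(run)
#' @export
run_scenario <- function(world, scenario = NULL, ref = NULL) {
  stopifnot(inherits(world, "fs_world"))
  is_ref <- is.null(scenario)
  if (!is_ref && is.null(ref)) {
    stop("dependency error: a REF run is required for substitution scenarios")
  }
  if (!is_ref) stopifnot(inherits(scenario, "fs_scenario"))

  regs <- world$config$regions
  years <- world$drivers$years
  crops <- world$commodities$crops
  animals <- world$commodities$animal_products

  land <- .initial_land(world)
  cohorts <- data.frame(region = character(), start_year = integer(),
                        area = numeric(), climate_zone = character(),
                        stringsAsFactors = FALSE)
  abandoned_pool <- stats::setNames(rep(0, length(regs)), regs)
  intensity <- stats::setNames(rep(1, length(regs)), regs)
  prev_prices <- NULL
  recipes <- default_recipes()
  oil_global <- vapply(regs, function(r) assign_oil(world, r, "global"), "")
  oil_local <- vapply(regs, function(r) assign_oil(world, r, "local"), "")

  steps <- vector("list", length(years))
  names(steps) <- years

  for (j in seq_along(years)) {
    yr <- years[j]
    drv <- project_drivers(world, yr)
    dem <- shift_demand(world, drv)

    fixed <- NULL; altq <- NULL; A <- NULL; caps <- NULL
    recipe_pick <- NULL
    if (!is_ref) {
      f <- substitution_fraction(substitution_schedule(scenario), yr)
      if (f > 0) {
        ref_sol <- ref$steps[[as.character(yr)]]$solution
        sub <- apply_substitution(ref_sol$consumption, scenario, yr,
                                  recipes, world)
        fixed <- sub$asf_food_demand
        altq <- sub$alt_demand
        oil <- if (scenario$sourcing == "local") oil_local else oil_global
        pr <- if (is.null(prev_prices)) {
          world$base_state$solution$prices
        } else prev_prices
        pick <- .choose_recipes(scenario, altq, pr, recipes, world, oil)
        recipe_pick <- pick$choice
        A <- pick$crop_demand
        if (scenario$sourcing == "local") {
          caps <- import_cap_constraints(scenario, ref_sol$imports,
                                         crops = crops)
        }
      }
    }

    inst <- build_market_instance(world, yr, demand = dem, land = land,
                                  intensity = intensity,
                                  fixed_food_demand = fixed,
                                  alt_crop_demand = A,
                                  import_caps = caps)
    sol <- solve_equilibrium(inst)

    ## land bookkeeping -------------------------------------------------------
    used_crop <- sol$land_used[, "cropland"]
    used_grass <- sol$land_used[, "grassland"]
    conv <- sol$conversions
    nat <- land[, "forest"] + land[, "other_natural"]
    fshare <- ifelse(nat > 0, land[, "forest"] / pmax(nat, 1e-12), 0)
    convN <- conv[, "n2c"] + conv[, "n2g"]
    aband_crop <- pmax(land[, "cropland"] + conv[, "n2c"] + conv[, "g2c"] +
                         conv[, "a2c"] - used_crop, 0)
    aband_grass <- pmax(land[, "grassland"] - conv[, "g2c"] + conv[, "n2g"] +
                          conv[, "a2g"] - used_grass, 0)
    aband_crop[aband_crop < 1e-6] <- 0    # solver-slack dust
    aband_grass[aband_grass < 1e-6] <- 0

    transitions <- .transition_record(regs, land, conv, fshare,
                                      aband_crop, aband_grass)

    new_aband <- aband_crop + aband_grass
    alloc <- allocate_restoration(new_aband, world$regions,
                                  list(min = world$calib$rest_min,
                                       max = world$calib$rest_max),
                                  year = yr)
    if (nrow(alloc$cohorts) > 0) cohorts <- rbind(cohorts, alloc$cohorts)
    unrestored <- alloc$unrestored

    land_next <- land
    land_next[, "cropland"] <- used_crop
    land_next[, "grassland"] <- used_grass
    land_next[, "forest"] <- land[, "forest"] - convN * fshare
    land_next[, "other_natural"] <- land[, "other_natural"] -
      convN * (1 - fshare)
    land_next[, "abandoned"] <- land[, "abandoned"] - conv[, "a2c"] -
      conv[, "a2g"] + unrestored
    land_next[, "restored"] <- land[, "restored"] + alloc$restored
    land_next <- pmax(land_next, 0)     # guard against FP dust
    abandoned_pool <- abandoned_pool + unrestored

    ledger <- list(cohorts = cohorts, abandoned_pool = abandoned_pool)

    ## accounts ---------------------------------------------------------------
    em <- agricultural_emissions(sol, world, intensity = intensity)
    luc <- land_use_change_co2(transitions, world$calib$carbon_stock,
                               step_years = 10)
    seq_sink <- sequestration(ledger,
                              list(cmax = world$calib$rest_cmax,
                                   k = world$calib$rest_k),
                              year = yr + 10, step_years = 10,
                              zones = world$regions$climate_zone)
    nitro <- nitrogen_inputs(sol, world)
    h2o <- water_use(sol, world$calib$water_coef)
    bii <- compute_bii(land_next, ledger,
                       .bii_model(world), year = yr)
    fsx <- .food_security_step(world, sol, altq, drv, yr)

    steps[[j]] <- list(
      year = yr, land = land, land_after = land_next,
      solution = sol, transitions = transitions,
      emissions = em, luc_co2 = luc, restoration_sink = seq_sink,
      nitrogen = nitro, water = h2o, bii = bii,
      food_security = fsx,
      alt_demand = altq, recipe_choice = recipe_pick,
      intensity = intensity,
      restoration = ledger
    )

    ## recursive state --------------------------------------------------------
    land <- land_next
    lp <- world$calib$lr_rent_floor + sol$land_price[, "grassland"]
    ref_lp <- world$calib$lr_ref_price
    if (is.null(ref_lp)) ref_lp <- lp
    intensity <- livestock_intensity(
      lp, list(eta = world$calib$lr_eta, ref = ref_lp,
               bounds = world$calib$lr_bounds))
    prev_prices <- sol$prices
  }

  structure(list(
    world = world,
    scenario = scenario,
    scenario_id = if (is_ref) "REF" else scenario_id(scenario),
    years = years,
    steps = steps
  ), class = "fs_run")
}

.transition_record <- function(regs, land, conv, fshare,
                               aband_crop, aband_grass) {
  recs <- list()
  add <- function(from, to, area) {
    keep <- area > 1e-9
    if (any(keep)) {
      recs[[length(recs) + 1L]] <<- data.frame(
        region = regs[keep], from = from, to = to, area = area[keep],
        stringsAsFactors = FALSE)
    }
  }
  add("forest", "cropland", conv[, "n2c"] * fshare)
  add("other_natural", "cropland", conv[, "n2c"] * (1 - fshare))
  add("forest", "grassland", conv[, "n2g"] * fshare)
  add("other_natural", "grassland", conv[, "n2g"] * (1 - fshare))
  add("grassland", "cropland", conv[, "g2c"])
  add("abandoned", "cropland", conv[, "a2c"])
  add("abandoned", "grassland", conv[, "a2g"])
  add("cropland", "abandoned", aband_crop)
  add("grassland", "abandoned", aband_grass)
  if (length(recs) == 0) {
    return(data.frame(region = character(), from = character(),
                      to = character(), area = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

.bii_model <- function(world) {
  list(coef = world$calib$bii_coef,
       ceiling = world$calib$bii_recovery_ceiling,
       recovery_years = world$calib$bii_recovery_years)
}

.food_security_step <- function(world, sol, altq, drv, yr) {
  regs <- world$config$regions
  cal <- world$commodities$calorie_content
  q <- sol$consumption
  kcal <- rowSums(q * cal[, colnames(q), drop = FALSE]) * 1e9
  if (!is.null(altq)) {
    kcal <- kcal + rowSums(altq * cal[, colnames(altq), drop = FALSE]) * 1e9
  }
  dec <- kcal / (drv$population * 1e6) / 365
  base <- project_drivers(world, world$drivers$years[1])
  cv <- project_cv(world$calib$cv0,
                   income_ratio = drv$income_pc / base$income_pc,
                   rate = world$calib$cv_rate, floor = world$calib$cv_floor)
  yi <- as.character(yr)
  shares <- cbind(child = world$calib$mder_share_child[, yi],
                  adult = world$calib$mder_share_adult[, yi],
                  elderly = world$calib$mder_share_elderly[, yi])
  mder <- project_mder(world$calib$mder_groups, shares)
  pou <- prevalence_of_undernourishment(
    dec = dec, cv = cv, mder = mder,
    high_income = world$regions$high_income,
    population = drv$population * 1e6)
  list(dec = dec, cv = cv, mder = mder,
       pou = pou$pou, headcount = pou$headcount)
}
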