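# ---- prevalence of undernourishment ----------------------------------------

#' Prevalence of undernourishment (log-normal model)
#'
#' Dietary energy consumption within a region is assumed log-normally
#' distributed with mean \code{dec} and coefficient of variation \code{cv};
#' the prevalence of undernourishment is the probability mass below the
#' minimum dietary energy requirement:
#' \deqn{\sigma^2 = \ln(1 + CV^2),\quad \mu = \ln(DEC) - \sigma^2/2,\quad
#'   PoU = \Phi\left(\frac{\ln MDER - \mu}{\sigma}\right).}
#' High-income regions are assigned zero risk of hunger.
#'
#' @param dec Mean dietary energy availability, kcal/person/day (> 0).
#' @param cv Coefficient of variation of the distribution (> 0).
#' @param mder Minimum dietary energy requirement, kcal/person/day (> 0).
#' @param high_income Logical (vectorized): zero prevalence when TRUE.
#' @param population Optional population (persons) for headcounts.
#' @return List with \code{pou} in [0, 1] and \code{headcount} (persons;
#'   NULL when population is not given).
#' @examples
#' prevalence_of_undernourishment(2800, 0.25, 1800)$pou  # about 0.047
#' @export
prevalence_of_undernourishment <- function(dec, cv, mder,
                                           high_income = FALSE,
                                           population = NULL) {
  if (any(dec <= 0) || any(cv <= 0) || any(mder <= 0)) {
    stop("domain error: DEC, CV and MDER must be positive")
  }
  sigma2 <- log(1 + cv^2)
  sigma <- sqrt(sigma2)
  mu <- log(dec) - sigma2 / 2
  pou <- stats::pnorm((log(mder) - mu) / sigma)
  pou[rep_len(high_income, length(pou))] <- 0
  names(pou) <- names(dec)
  list(pou = pou,
       headcount = if (is.null(population)) NULL else pou * population)
}

#' Project the coefficient of variation with income growth
#'
#' Equity of the food distribution improves with income growth: the gap of
#' the CV above its floor shrinks linearly by \code{rate} per 10 per cent of
#' cumulative income gain, down to the floor (the present best value, 0.2).
#' Constant income leaves the CV unchanged; income declines do not worsen it.
#'
#' @param base_cv Base-year CV (values below the floor are clamped to the
#'   floor with a warning).
#' @param income_ratio Income per capita relative to the base year
#'   (vectorized over regions).
#' @param rate Gap reduction per 10 per cent income gain (default 0.02).
#' @param floor Lower bound of the CV (default 0.2).
#' @return Projected CV, same length as the inputs.
#' @export
project_cv <- function(base_cv, income_ratio, rate = 0.02, floor = 0.2) {
  if (any(base_cv < floor)) {
    warning("base CV below the floor of ", floor, "; clamped")
    base_cv <- pmax(base_cv, floor)
  }
  shrink <- pmin(pmax(1 - rate * (income_ratio - 1) / 0.1, 0), 1)
  pmax(floor + (base_cv - floor) * shrink, floor)
}

#' Project the minimum dietary energy requirement
#'
#' Demographic-weighted mean of group-specific requirements.
#'
#' @param group_mder Named vector of kcal/person/day per demographic group.
#' @param shares Vector (or matrix, regions x groups) of population shares;
#'   each row must sum to 1.
#' @return MDER per region (or a scalar for a vector of shares).
#' @export
project_mder <- function(group_mder, shares) {
  if (is.null(dim(shares))) shares <- matrix(shares, 1,
                                             dimnames = list(NULL,
                                                             names(shares)))
  if (any(abs(rowSums(shares) - 1) > 1e-6)) {
    stop("domain error: demographic shares must sum to 1")
  }
  out <- drop(shares[, names(group_mder), drop = FALSE] %*% group_mder)
  out
}

# ---- price indices ----------------------------------------------------------

#' Paasche price index
#'
#' Current-quantity-weighted price index
#' \eqn{\sum p_1 q_1 / \sum p_0 q_1} over the non-excluded commodities
#' (novel-alternative prices are excluded from the reported food price
#' indices).
#'
#' @param p0,p1 Named base-period and current prices.
#' @param q1 Named current quantities.
#' @param exclude Commodities to drop from the basket.
#' @return The index (1 = unchanged prices).
#' @examples
#' paasche_index(c(a = 2, b = 3), c(a = 3, b = 3), c(a = 1, b = 2))  # 1.125
#' @export
paasche_index <- function(p0, p1, q1, exclude = NULL) {
  keep <- setdiff(names(q1), exclude)
  if (any(p0[keep] < 0, na.rm = TRUE) || any(q1[keep] < 0, na.rm = TRUE)) {
    stop("domain error: negative prices or quantities")
  }
  den <- sum(p0[keep] * q1[keep])
  if (!is.finite(den) || den <= 0) {
    stop("domain error: zero base-price value of the current basket")
  }
  sum(p1[keep] * q1[keep]) / den
}

# ---- indicator reporting ----------------------------------------------------

#' Tidy indicator table of one or more runs
#'
#' Collects the reported indicators of completed runs into one long table:
#' ASF and alternative consumption, crop use by purpose, Paasche price
#' indices (alternatives excluded), prevalence of undernourishment and
#' headcounts, land areas, emissions by source, land-use-change CO2,
#' restoration sink, nitrogen, water, BII and restored area; per scenario,
#' year and region plus a \code{GLO} aggregate (sums; area-weighted mean for
#' BII; headcount-based PoU).
#'
#' @param runs An \code{fs_run} or a list of them (same world).
#' @return A data frame with columns scenario_id, year, region, indicator,
#'   unit, value.
#' @export
report_indicators <- function(runs) {
  if (inherits(runs, "fs_run")) runs <- list(runs)
  seeds <- vapply(runs, function(r) r$world$seed, integer(1))
  cfg <- vapply(runs, function(r) paste(r$world$config$regions,
                                        collapse = ","), "")
  if (length(unique(seeds)) > 1 || length(unique(cfg)) > 1) {
    stop("consistency error: runs come from different worlds")
  }
  rows <- list()
  emit <- function(scen, year, region, indicator, unit, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario_id = scen, year = year, region = region,
      indicator = indicator, unit = unit, value = unname(value),
      stringsAsFactors = FALSE)
  }
  for (run in runs) {
    sid <- run$scenario_id
    world <- run$world
    regs <- world$config$regions
    base_sol <- run$steps[[1]]$solution
    crops <- world$commodities$crops
    animals <- world$commodities$animal_products
    pop0 <- project_drivers(world, run$years[1])$population
    for (st in run$steps) {
      yr <- st$year
      sol <- st$solution
      drv <- project_drivers(world, yr)
      for (p in animals) {
        emit(sid, yr, regs, paste0("consumption|", p), "Mt",
             sol$consumption[, p])
        emit(sid, yr, "GLO", paste0("consumption|", p), "Mt",
             sum(sol$consumption[, p]))
      }
      if (!is.null(st$alt_demand)) {
        for (p in colnames(st$alt_demand)) {
          emit(sid, yr, regs, paste0("alt_consumption|", p), "Mt",
               st$alt_demand[, p])
          emit(sid, yr, "GLO", paste0("alt_consumption|", p), "Mt",
               sum(st$alt_demand[, p]))
        }
      }
      use <- cbind(food = rowSums(sol$consumption[, crops, drop = FALSE]),
                   feed = rowSums(sol$feed_use),
                   alt_ingredient = rowSums(sol$alt_ingredient_use))
      for (u in colnames(use)) {
        emit(sid, yr, regs, paste0("crop_use|", u), "Mt", use[, u])
        emit(sid, yr, "GLO", paste0("crop_use|", u), "Mt", sum(use[, u]))
      }
      for (grp in list(list(nm = "crops", set = crops),
                       list(nm = "asf", set = animals))) {
        idx <- vapply(regs, function(r) {
          paasche_index(base_sol$prices[r, grp$set], sol$prices[r, grp$set],
                        sol$consumption[r, grp$set])
        }, numeric(1))
        emit(sid, yr, regs, paste0("price_index|", grp$nm), "index", idx)
        gq <- colSums(sol$consumption[, grp$set, drop = FALSE])
        gp0 <- colSums(base_sol$prices[, grp$set, drop = FALSE] *
                         sol$consumption[, grp$set, drop = FALSE]) /
          pmax(gq, 1e-12)
        gp1 <- colSums(sol$prices[, grp$set, drop = FALSE] *
                         sol$consumption[, grp$set, drop = FALSE]) /
          pmax(gq, 1e-12)
        emit(sid, yr, "GLO", paste0("price_index|", grp$nm), "index",
             paasche_index(gp0, gp1, gq))
      }
      fsx <- st$food_security
      emit(sid, yr, regs, "pou", "fraction", fsx$pou)
      emit(sid, yr, "GLO", "pou", "fraction",
           sum(fsx$headcount) / sum(drv$population * 1e6))
      emit(sid, yr, regs, "headcount", "millions", fsx$headcount / 1e6)
      emit(sid, yr, "GLO", "headcount", "millions", sum(fsx$headcount) / 1e6)
      for (cl in colnames(st$land_after)) {
        emit(sid, yr, regs, paste0("land|", cl), "Mha", st$land_after[, cl])
        emit(sid, yr, "GLO", paste0("land|", cl), "Mha",
             sum(st$land_after[, cl]))
      }
      ag <- stats::aggregate(value ~ region + source, st$emissions, sum)
      for (src in unique(ag$source)) {
        v <- stats::setNames(rep(0, length(regs)), regs)
        sub <- ag[ag$source == src, ]
        v[sub$region] <- sub$value
        emit(sid, yr, regs, paste0("emissions|", src), "MtCO2eq/yr", v)
        emit(sid, yr, "GLO", paste0("emissions|", src), "MtCO2eq/yr", sum(v))
      }
      emit(sid, yr, regs, "emissions|luc_co2", "MtCO2eq/yr", st$luc_co2)
      emit(sid, yr, "GLO", "emissions|luc_co2", "MtCO2eq/yr",
           sum(st$luc_co2))
      sink <- stats::setNames(rep(0, length(regs)), regs)
      if (length(st$restoration_sink) > 0) {
        sink[names(st$restoration_sink)] <- st$restoration_sink * 1000
      }
      emit(sid, yr, regs, "emissions|restoration_sink", "MtCO2eq/yr", sink)
      emit(sid, yr, "GLO", "emissions|restoration_sink", "MtCO2eq/yr",
           sum(sink))
      tot_ag <- tapply(st$emissions$value, st$emissions$region, sum)[regs]
      emit(sid, yr, regs, "emissions|total", "MtCO2eq/yr",
           tot_ag + st$luc_co2 - sink)
      emit(sid, yr, "GLO", "emissions|total", "MtCO2eq/yr",
           sum(tot_ag + st$luc_co2 - sink))
      emit(sid, yr, regs, "nitrogen|total_input", "MtN/yr",
           st$nitrogen$total_n_input)
      emit(sid, yr, "GLO", "nitrogen|total_input", "MtN/yr",
           sum(st$nitrogen$total_n_input))
      emit(sid, yr, regs, "nitrogen|manure_applied", "MtN/yr",
           st$nitrogen$manure_n_applied)
      emit(sid, yr, "GLO", "nitrogen|manure_applied", "MtN/yr",
           sum(st$nitrogen$manure_n_applied))
      emit(sid, yr, regs, "water", "km3/yr", st$water)
      emit(sid, yr, "GLO", "water", "km3/yr", sum(st$water))
      emit(sid, yr, regs, "bii", "index", st$bii$by_region)
      emit(sid, yr, "GLO", "bii", "index", st$bii$global)
      emit(sid, yr, regs, "restored_area", "Mha", st$land_after[, "restored"])
      emit(sid, yr, "GLO", "restored_area", "Mha",
           sum(st$land_after[, "restored"]))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$scenario_id, out$year, out$indicator, out$region), ]
  rownames(out) <- NULL
  out
}
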