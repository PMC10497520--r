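# ---- greenhouse gases -------------------------------------------------------

#' Agricultural non-CO2 emissions
#'
#' Activity-based accounting of the agricultural greenhouse-gas sources:
#' enteric CH4 (scaled by the ruminant intensity multiplier), manure
#' management CH4 and N2O, N2O from manure dropped on pastures, N2O from
#' nitrogen applied to soils (fertilizer and manure) and CH4 from rice
#' cultivation.  Gases are aggregated to CO2-equivalents with GWP100
#' constants (defaults CH4 = 28, N2O = 265).
#'
#' @param solution An \code{fs_equilibrium}.
#' @param world The \code{fs_world} holding the emission factors, or a list
#'   with the same \code{calib} fields.
#' @param intensity Named per-region ruminant intensity multipliers (enteric
#'   intensity is divided by them); default 1.
#' @return An emission ledger: data frame (region, gas, source, value) with
#'   value in Mt CO2eq/yr; additive over regions and sources.
#' @export
agricultural_emissions <- function(solution, world, intensity = NULL) {
  cal <- world$calib
  x <- solution$production
  regs <- rownames(x)
  animals <- colnames(cal$ef_enteric)
  crops <- colnames(cal$n_harvest)
  if (is.null(intensity)) intensity <- stats::setNames(rep(1, length(regs)),
                                                       regs)
  xa <- x[, animals, drop = FALSE]
  if (anyNA(cal$ef_enteric) || anyNA(cal$ef_manure_ch4)) {
    stop("accounting error: missing emission factor for an active activity")
  }
  ruminant <- cal$grass_req[1, ] > 0

  k <- (solution$year - world$drivers$years[1]) / 10
  lpg <- cal$livestock_productivity_growth^k
  ef_ent <- cal$ef_enteric
  ef_ent[, ruminant] <- sweep(ef_ent[, ruminant, drop = FALSE], 1,
                              intensity * lpg, "/")
  enteric_ch4 <- rowSums(xa * ef_ent)                       # Mt CH4
  manure_ch4 <- rowSums(xa * cal$ef_manure_ch4)

  excreted <- xa * cal$n_excretion                          # Mt N
  pasture_n <- rowSums(excreted * cal$n_pasture_share)
  managed_n <- rowSums(excreted * (1 - cal$n_pasture_share))
  pasture_n2o <- pasture_n * cal$ef_n2o_pasture
  manure_n2o <- managed_n * 0.002 * 44 / 28                 # management losses

  nin <- nitrogen_inputs(solution, world)
  soil_n2o <- nin$total_n_input * cal$ef_n2o_soil

  rice_area <- x[, "rice"] / .solution_yield(solution, world, "rice")
  rice_ch4 <- rice_area * cal$ef_rice_ch4                   # Mha * t/ha = Mt

  g <- function(source, gas, mt_gas, gwp) {
    data.frame(region = regs, gas = gas, source = source,
               value = mt_gas * gwp, stringsAsFactors = FALSE)
  }
  ledger <- rbind(
    g("enteric_fermentation", "CH4", enteric_ch4, cal$gwp_ch4),
    g("manure_management", "CH4", manure_ch4, cal$gwp_ch4),
    g("manure_management", "N2O", manure_n2o, cal$gwp_n2o),
    g("manure_on_pasture", "N2O", pasture_n2o, cal$gwp_n2o),
    g("soil_n", "N2O", soil_n2o, cal$gwp_n2o),
    g("rice_cultivation", "CH4", rice_ch4, cal$gwp_ch4)
  )
  rownames(ledger) <- NULL
  ledger
}

# per-region realized yield for one crop at the solution's year
.solution_yield <- function(solution, world, crop) {
  k <- (solution$year - world$drivers$years[1]) / 10
  world$calib$yield[, crop] * world$calib$yield_growth^k
}

#' Land-use-change CO2 flux
#'
#' Stock-difference accounting: each recorded transition releases (or would
#' absorb) the difference in carbon density between source and target class,
#' spread linearly over the decadal step.  Transitions to the abandoned pool
#' are carbon-neutral (regrowth is credited only through explicit
#' restoration).
#'
#' @param transitions Data frame (region, from, to, area in Mha).
#' @param stocks Matrix (regions x land classes) of carbon densities, t C/ha.
#' @param step_years Length of the step the transition is spread over.
#' @return Named vector, Mt CO2/yr by region (regions present in
#'   \code{transitions}; missing regions are zero).
#' @export
land_use_change_co2 <- function(transitions, stocks, step_years = 10) {
  regs <- rownames(stocks)
  out <- stats::setNames(numeric(length(regs)), regs)
  if (nrow(transitions) == 0) return(out)
  for (i in seq_len(nrow(transitions))) {
    fr <- transitions$from[i]; to <- transitions$to[i]
    if (to == "abandoned") next                     # carbon-neutral pool
    if (!fr %in% colnames(stocks) || !to %in% colnames(stocks)) {
      stop("accounting error: undefined carbon stock for class ",
           if (!fr %in% colnames(stocks)) fr else to)
    }
    r <- transitions$region[i]
    dC <- stocks[r, fr] - stocks[r, to]             # t C/ha
    out[r] <- out[r] + transitions$area[i] * dC * 44 / 12 / step_years
  }
  out
}

# ---- nitrogen ---------------------------------------------------------------

#' Nitrogen inputs to cropland
#'
#' Total cropland nitrogen input is harvested crop nitrogen divided by the
#' nitrogen use efficiency; manure nitrogen applied to cropland is livestock
#' excretion not dropped on pasture, times the manure-management efficiency.
#' The two are separate accounts (manure is a component of the total input,
#' not an addition to it).
#'
#' @param solution An \code{fs_equilibrium}.
#' @param world The \code{fs_world} with nitrogen parameters.
#' @return Data frame (region, total_n_input, manure_n_applied), Mt N/yr.
#' @export
nitrogen_inputs <- function(solution, world) {
  cal <- world$calib
  crops <- colnames(cal$n_harvest)
  animals <- colnames(cal$n_excretion)
  x <- solution$production
  if (any(cal$n_nue <= 0)) {
    stop("accounting error: nitrogen use efficiency must be positive")
  }
  harvested <- x[, crops, drop = FALSE] * cal$n_harvest
  total <- rowSums(harvested / cal$n_nue)
  xa <- x[, animals, drop = FALSE]
  manure <- rowSums(xa * cal$n_excretion * (1 - cal$n_pasture_share) *
                      cal$n_mm_eff)
  data.frame(region = rownames(x), total_n_input = total,
             manure_n_applied = manure, stringsAsFactors = FALSE)
}

# ---- water ------------------------------------------------------------------

#' Agricultural water use
#'
#' Production times water-use coefficients, converted to cubic kilometres.
#'
#' @param solution An \code{fs_equilibrium}.
#' @param coefficients Matrix (regions x commodities), cubic metres per tonne.
#' @return Named vector, km3/yr by region.
#' @export
water_use <- function(solution, coefficients) {
  x <- solution$production
  cc <- colnames(x)
  if (!all(cc %in% colnames(coefficients))) {
    stop("accounting error: missing water coefficient for ",
         paste(setdiff(cc, colnames(coefficients)), collapse = ", "))
  }
  co <- coefficients[rownames(x), cc, drop = FALSE]
  if (anyNA(co)) stop("accounting error: missing water coefficient")
  rowSums(x * co) / 1000      # Mt * m3/t = 1e6 m3 = 1e-3 km3
}
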