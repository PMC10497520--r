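# ---- S3 methods -------------------------------------------------------------

#' @export
print.fs_config <- function(x, ...) {
  cat("World configuration:", length(x$regions), "regions,",
      paste(range(x$years), collapse = "-"), "decadal, noise_sd =",
      x$noise_sd, "\n")
  invisible(x)
}

#' @export
print.fs_world <- function(x, ...) {
  cat("Synthetic world baseline (seed ", x$seed, ")\n", sep = "")
  cat("  regions:    ", length(x$config$regions), " (",
      paste(x$config$regions, collapse = ", "), ")\n", sep = "")
  cat("  commodities:", length(x$commodities$crops), "crops,",
      length(x$commodities$animal_products), "animal products\n")
  cat("  years:      ", paste(x$drivers$years, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fs_world <- function(object, ...) {
  x <- object
  sol <- x$base_state$solution
  cat("Synthetic world baseline (seed ", x$seed, "), base year ",
      x$drivers$years[1], "\n", sep = "")
  cat("  population: ", round(sum(x$drivers$population[, 1])),
      " million; income pc range ",
      paste(round(range(x$drivers$income_pc[, 1]), 1), collapse = "-"),
      " kUSD\n", sep = "")
  land <- .initial_land(x)
  cat("  land (Mha): ",
      paste(colnames(land), round(colSums(land)), collapse = ", ", sep = " "),
      "\n", sep = "")
  if (!is.null(sol)) {
    cat("  base production (Mt): crops ",
        round(sum(sol$production[, x$commodities$crops])),
        ", animal products ",
        round(sum(sol$production[, x$commodities$animal_products])), "\n",
        sep = "")
    cat("  base welfare: ", format(sol$welfare, big.mark = ","),
        " million USD\n", sep = "")
  }
  invisible(x)
}

#' @export
print.fs_scenario <- function(x, ...) {
  cat("Scenario ", scenario_id(x), "\n", sep = "")
  cat("  scope: ", x$scope, "; products: ",
      paste(x$products, collapse = ", "), "\n", sep = "")
  cat("  recipe rule: ", x$recipe_rule, "; level: ", x$level,
      " by ", x$end_year, "; sourcing: ", x$sourcing, "; processing: ",
      x$processing, "\n", sep = "")
  invisible(x)
}

#' @export
print.fs_equilibrium <- function(x, ...) {
  cat("Market equilibrium, year ", x$year, "\n", sep = "")
  cat("  welfare: ", format(round(x$welfare), big.mark = ","),
      " million USD; solver iterations: ", x$iterations[1], "\n", sep = "")
  cat("  max |clearing residual|: ",
      format(max(abs(x$clearing_residual)), digits = 3), " Mt\n", sep = "")
  invisible(x)
}

#' @export
print.fs_recipe <- function(x, ...) {
  cat("Recipe ", x$id, " (replaces ", x$product, ")\n", sep = "")
  for (i in seq_len(nrow(x$ingredients))) {
    cat(sprintf("  %-28s %5.1f%%  (%s)\n", x$ingredients$ingredient[i],
                100 * x$ingredients$share[i], x$ingredients$role[i]))
  }
  if (x$oil_share > 0) {
    cat(sprintf("  %-28s %5.1f%%  (oil)\n", "vegetable oil (regional)",
                100 * x$oil_share))
  }
  cat(sprintf("  water remainder              %5.1f%%\n",
              100 * water_share(x)))
  invisible(x)
}

#' @export
print.fs_run <- function(x, ...) {
  cat("Scenario run ", x$scenario_id, ": ",
      length(x$steps), " steps (", paste(range(x$years), collapse = "-"),
      ")\n", sep = "")
  invisible(x)
}

#' @export
summary.fs_run <- function(object, ...) {
  x <- object
  cat("Scenario run ", x$scenario_id, "\n", sep = "")
  hdr <- sprintf("  %-6s %12s %12s %10s %8s %8s",
                 "year", "ASF cons Mt", "GHG MtCO2eq", "conv Mha",
                 "BII", "PoU %")
  cat(hdr, "\n")
  animals <- x$world$commodities$animal_products
  for (st in x$steps) {
    ag <- sum(st$emissions$value) + sum(st$luc_co2) -
      1000 * sum(st$restoration_sink)
    drv <- project_drivers(x$world, st$year)
    pou <- 100 * sum(st$food_security$headcount) /
      sum(drv$population * 1e6)
    cat(sprintf("  %-6d %12.1f %12.0f %10.2f %8.4f %8.2f\n", st$year,
                sum(st$solution$consumption[, animals]), ag,
                sum(st$solution$conversions[, c("n2c", "n2g")]),
                st$bii$global, pou))
  }
  invisible(x)
}

#' Trajectory plots of a scenario run
#'
#' Four base-graphics panels: total agriculture and land-use emissions
#' (including the restoration sink), land conversion and restored area,
#' global BII, and global prevalence of undernourishment.
#'
#' @param x An \code{fs_run}.
#' @param ... Passed to \code{plot}.
#' @export
plot.fs_run <- function(x, ...) {
  yrs <- x$years
  ghg <- vapply(x$steps, function(st) {
    sum(st$emissions$value) + sum(st$luc_co2) - 1000 *
      sum(st$restoration_sink)
  }, numeric(1))
  conv <- vapply(x$steps, function(st) {
    sum(st$solution$conversions[, c("n2c", "n2g")])
  }, numeric(1))
  rest <- vapply(x$steps, function(st) sum(st$land_after[, "restored"]),
                 numeric(1))
  bii <- vapply(x$steps, function(st) st$bii$global, numeric(1))
  pou <- vapply(x$steps, function(st) {
    drv <- project_drivers(x$world, st$year)
    100 * sum(st$food_security$headcount) / sum(drv$population * 1e6)
  }, numeric(1))
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(yrs, ghg, type = "b", xlab = "year",
       ylab = "Mt CO2eq/yr", main = "AFOLU emissions (net)", ...)
  graphics::matplot(yrs, cbind(conv, rest), type = "b", pch = c(1, 2),
                    lty = 1, xlab = "year", ylab = "Mha",
                    main = "Conversion (o) / restored (tri)")
  plot(yrs, bii, type = "b", xlab = "year", ylab = "BII",
       main = "Biodiversity intactness")
  plot(yrs, pou, type = "b", xlab = "year", ylab = "PoU (%)",
       main = "Undernourishment")
  invisible(x)
}
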