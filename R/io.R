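# ---- world export / import --------------------------------------------------

# flatten a list of scalars / named vectors / matrices into one long table
.flat_to_df <- function(lst) {
  rows <- lapply(names(lst), function(nm) {
    x <- lst[[nm]]
    if (is.matrix(x)) {
      data.frame(block = nm,
                 row = rep(rownames(x), ncol(x)),
                 col = rep(colnames(x), each = nrow(x)),
                 value = as.vector(x), stringsAsFactors = FALSE)
    } else if (length(x) > 1 || !is.null(names(x))) {
      rn <- names(x)
      if (is.null(rn)) rn <- as.character(seq_along(x))
      data.frame(block = nm, row = rn, col = NA_character_,
                 value = as.vector(x), stringsAsFactors = FALSE)
    } else {
      data.frame(block = nm, row = NA_character_, col = NA_character_,
                 value = as.vector(x), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

.df_to_flat <- function(df) {
  out <- list()
  for (nm in unique(df$block)) {
    d <- df[df$block == nm, , drop = FALSE]
    if (all(is.na(d$col))) {
      if (nrow(d) == 1 && is.na(d$row[1])) {
        out[[nm]] <- d$value
      } else {
        out[[nm]] <- stats::setNames(d$value, d$row)
      }
    } else {
      rn <- unique(d$row); cn <- unique(d$col)
      m <- matrix(NA_real_, length(rn), length(cn),
                  dimnames = list(rn, cn))
      m[cbind(match(d$row, rn), match(d$col, cn))] <- d$value
      out[[nm]] <- m
    }
  }
  out
}

#' Export / import a generated world as tidy CSV tables
#'
#' Writes the seeded, world-specific content (configuration, regional
#' attributes, driver trajectories, all calibration blocks and the solved
#' base-year state) to a directory of plain-text files; \code{import_world}
#' reconstructs an equivalent \code{fs_world}.  The fixed nutrient and
#' conversion fixtures are not serialized (they are deterministic package
#' data).
#'
#' @param world An \code{fs_world}.
#' @param dir Directory to write to / read from (created if needed).
#' @return \code{import_world} returns an \code{fs_world};
#'   \code{export_world} returns \code{dir} invisibly.
#' @export
export_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(regions = world$config$regions,
                        years = world$drivers$years,
                        noise_sd = world$config$noise_sd,
                        seed = world$seed),
                   file.path(dir, "config.yaml"))
  utils::write.csv(world$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  drv <- .flat_to_df(list(population = world$drivers$population,
                          income_pc = world$drivers$income_pc))
  utils::write.csv(drv, file.path(dir, "drivers.csv"), row.names = FALSE)
  # lr_ref_price is appended after the base solve; keep ordering stable
  utils::write.csv(.flat_to_df(world$calib),
                   file.path(dir, "calibration.csv"), row.names = FALSE)
  utils::write.csv(.flat_to_df(world$commodities["calorie_content"]),
                   file.path(dir, "calories.csv"), row.names = FALSE)
  sol <- world$base_state$solution
  base <- list(consumption = sol$consumption, production = sol$production,
               imports = sol$imports, exports = sol$exports,
               feed_use = sol$feed_use,
               alt_ingredient_use = sol$alt_ingredient_use,
               conversions = sol$conversions, prices = sol$prices,
               land_price = sol$land_price, land_used = sol$land_used,
               clearing_residual = sol$clearing_residual,
               welfare = sol$welfare, year = sol$year,
               iterations = sol$iterations[1])
  utils::write.csv(.flat_to_df(base), file.path(dir, "base_state.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname export_world
#' @export
import_world <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- world_config(regions = cfg$regions, years = cfg$years,
                         noise_sd = cfg$noise_sd)
  regions <- utils::read.csv(file.path(dir, "regions.csv"),
                             stringsAsFactors = FALSE)
  rownames(regions) <- regions$region
  drv <- .df_to_flat(utils::read.csv(file.path(dir, "drivers.csv"),
                                     stringsAsFactors = FALSE))
  calib <- .df_to_flat(utils::read.csv(file.path(dir, "calibration.csv"),
                                       stringsAsFactors = FALSE))
  cal <- .df_to_flat(utils::read.csv(file.path(dir, "calories.csv"),
                                     stringsAsFactors = FALSE))
  base <- .df_to_flat(utils::read.csv(file.path(dir, "base_state.csv"),
                                      stringsAsFactors = FALSE))
  sol <- structure(base[c("consumption", "production", "imports", "exports",
                          "feed_use", "alt_ingredient_use", "conversions",
                          "prices", "land_price", "land_used",
                          "clearing_residual")],
                   class = "fs_equilibrium")
  sol$welfare <- base$welfare; sol$year <- base$year
  sol$iterations <- base$iterations
  world <- structure(list(
    config = config, seed = as.integer(cfg$seed), regions = regions,
    commodities = list(crops = fs_crops(),
                       animal_products = fs_animal_products(),
                       oil_crops = fs_oil_crops(),
                       calorie_content = cal$calorie_content),
    drivers = list(years = config$years, population = drv$population,
                   income_pc = drv$income_pc),
    nutrients = default_nutrients(),
    conversions = default_conversions(),
    calib = calib,
    base_state = NULL), class = "fs_world")
  world$base_state <- .make_state(world, config$years[1], sol,
                                  land = .initial_land(world))
  world
}

#' Export an equilibrium solution as tidy CSV
#'
#' One row per (variable, region, commodity/class) with units, suitable for
#' regression tests and external analysis.
#'
#' @param solution An \code{fs_equilibrium}.
#' @param file Path to write.
#' @param scenario_id Tag recorded in the output.
#' @return The data frame, invisibly.
#' @export
export_solution <- function(solution, file, scenario_id = "REF") {
  blocks <- list(consumption = "Mt", production = "Mt", imports = "Mt",
                 exports = "Mt", feed_use = "Mt", alt_ingredient_use = "Mt",
                 conversions = "Mha", prices = "USD/t",
                 land_price = "USD/ha", land_used = "Mha")
  rows <- lapply(names(blocks), function(b) {
    m <- solution[[b]]
    data.frame(scenario_id = scenario_id, year = solution$year,
               variable = b,
               region = rep(rownames(m), ncol(m)),
               item = rep(colnames(m), each = nrow(m)),
               unit = blocks[[b]], value = as.vector(m),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
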