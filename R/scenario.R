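# ---- scenario specification -------------------------------------------------

#' Define a substitution scenario
#'
#' One point in the six-dimension scenario space: regional scope, product set,
#' recipe rule, substitution level, ingredient sourcing and processing
#' efficiency.
#'
#' @param scope \code{"GLOB"} (global substitution) or one macro-region code
#'   (single-region scenario).
#' @param products Animal products substituted: a subset of
#'   \code{fs_substitutable()}, or \code{"ALL"}.
#' @param recipe_rule A fixed recipe id (single-product scenarios) or
#'   \code{"ENDOGENOUS"} (least-cost choice, all-product scenarios only).
#' @param level Substitution level s reached by 2050, one of 0.10, 0.25,
#'   0.50, 0.90 (other values in [0, 1] are allowed; 0 reproduces REF).
#' @param sourcing \code{"global"} or \code{"local"} (imports capped at REF).
#' @param processing \code{"inefficient"} or \code{"efficient"} by-product
#'   accounting.
#' @param start_year First year with non-zero substitution on the decadal
#'   grid (default 2030); the ramp is linear from the base year.
#' @param end_year Year by which the target level is reached (default 2050).
#' @return An object of class \code{fs_scenario}.
#' @examples
#' scenario_spec(level = 0.5)                      # GLOB_ALL_ENDO_L50
#' scenario_spec(products = "beef", recipe_rule = "B1", level = 0.25)
#' @export
scenario_spec <- function(scope = "GLOB", products = "ALL",
                          recipe_rule = "ENDOGENOUS", level = 0.5,
                          sourcing = c("global", "local"),
                          processing = c("inefficient", "efficient"),
                          start_year = 2030, end_year = 2050) {
  sourcing <- match.arg(sourcing)
  processing <- match.arg(processing)
  if (!identical(scope, "GLOB") && !(scope %in% fs_regions())) {
    stop("configuration error: scope must be 'GLOB' or a macro-region code")
  }
  if (identical(products, "ALL")) products <- fs_substitutable()
  if (length(products) == 0) {
    stop("configuration error: empty product set")
  }
  if (!all(products %in% fs_substitutable())) {
    stop("configuration error: products must be drawn from ",
         paste(fs_substitutable(), collapse = ", "))
  }
  if (!is.numeric(level) || level < 0 || level > 1) {
    stop("configuration error: substitution level must be in [0, 1]")
  }
  all_products <- setequal(products, fs_substitutable())
  if (identical(recipe_rule, "ENDOGENOUS")) {
    if (!all_products) {
      stop("configuration error: ENDOGENOUS recipe selection requires the ",
           "full product set")
    }
  } else {
    rec <- default_recipes()
    if (!recipe_rule %in% names(rec)) {
      stop("configuration error: unknown recipe id ", recipe_rule)
    }
    if (!rec[[recipe_rule]]$product %in% products) {
      stop("configuration error: recipe ", recipe_rule,
           " does not match the product set")
    }
    if (length(products) > 1) {
      stop("configuration error: a fixed recipe requires a single product")
    }
  }
  structure(list(scope = scope, products = products,
                 recipe_rule = recipe_rule, level = level,
                 sourcing = sourcing, processing = processing,
                 start_year = start_year, end_year = end_year),
            class = "fs_scenario")
}

#' Canonical scenario identifier
#'
#' @param spec An \code{fs_scenario}.
#' @return A string such as \code{"GLOB_ALL_ENDO_L50_SRCG_PROCI"}.
#' @export
scenario_id <- function(spec) {
  prod <- if (setequal(spec$products, fs_substitutable())) {
    "ALL"
  } else paste(toupper(spec$products), collapse = "+")
  rec <- if (identical(spec$recipe_rule, "ENDOGENOUS")) "ENDO" else
    spec$recipe_rule
  paste0(spec$scope, "_", prod, "_", rec,
         "_L", formatC(round(spec$level * 100), width = 2, flag = "0"),
         "_SRC", toupper(substr(spec$sourcing, 1, 1)),
         "_PROC", toupper(substr(spec$processing, 1, 1)))
}

#' Build a grid of scenarios
#'
#' Cartesian product of the requested dimension values, subject to the recipe
#' constraint: fixed recipes pair only with their own single product, and
#' ENDOGENOUS pairs only with the full product set.  Ordering is
#' deterministic (dimension order as given, values in the order supplied).
#'
#' @param scope Character vector of scopes.
#' @param products Either \code{"ALL"} or a vector of single products; each
#'   entry becomes one product dimension value.
#' @param recipes Recipe rule values; default derives the permissible ones
#'   from the product dimension (all matching recipe ids for a single
#'   product, \code{"ENDOGENOUS"} for ALL).
#' @param levels Numeric substitution levels.
#' @param sourcing,processing Dimension values.
#' @return A list of \code{fs_scenario} objects.
#' @examples
#' length(build_scenario_grid(products = "beef",
#'                            levels = c(.1, .25, .5, .9)))  # 5*4*2*2 = 80
#' @export
build_scenario_grid <- function(scope = "GLOB", products = "ALL",
                                recipes = NULL,
                                levels = c(0.10, 0.25, 0.50, 0.90),
                                sourcing = c("global", "local"),
                                processing = c("inefficient", "efficient")) {
  if (length(products) == 0) {
    stop("configuration error: empty product set")
  }
  if (any(levels <= 0 | levels > 1)) {
    stop("configuration error: substitution levels must be in (0, 1]")
  }
  all_rec <- default_recipes()
  out <- list()
  for (sc in scope) for (p in products) {
    rr <- recipes
    if (is.null(rr)) {
      rr <- if (identical(p, "ALL")) "ENDOGENOUS" else
        names(all_rec)[vapply(all_rec, function(r) r$product == p,
                              logical(1))]
    } else if (!identical(p, "ALL")) {
      rr <- rr[rr %in% names(all_rec)[
        vapply(all_rec, function(r) r$product == p, logical(1))]]
    }
    for (rc in rr) for (lv in levels) for (so in sourcing) {
      for (pr in processing) {
        out[[length(out) + 1L]] <- scenario_spec(
          scope = sc, products = p, recipe_rule = rc, level = lv,
          sourcing = so, processing = pr)
      }
    }
  }
  names(out) <- vapply(out, scenario_id, "")
  out
}

#' Write or read a scenario grid as CSV
#'
#' One row per scenario (columns: scenario_id, scope, products, recipe_rule,
#' level, sourcing, processing).
#'
#' @param grid A list of \code{fs_scenario}.
#' @param file Path to a CSV file.
#' @return \code{read_scenario_grid} returns a list of \code{fs_scenario}.
#' @export
write_scenario_grid <- function(grid, file) {
  df <- do.call(rbind, lapply(grid, function(s) {
    data.frame(scenario_id = scenario_id(s), scope = s$scope,
               products = paste(s$products, collapse = "+"),
               recipe_rule = s$recipe_rule, level = s$level,
               sourcing = s$sourcing, processing = s$processing,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' @rdname write_scenario_grid
#' @export
read_scenario_grid <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    scenario_spec(scope = df$scope[i],
                  products = strsplit(df$products[i], "\\+")[[1]],
                  recipe_rule = df$recipe_rule[i], level = df$level[i],
                  sourcing = df$sourcing[i], processing = df$processing[i])
  })
  names(out) <- vapply(out, scenario_id, "")
  out
}

# ---- substitution schedule --------------------------------------------------

#' Substitution schedule of a scenario
#'
#' The substituted fraction ramps linearly from zero in the base year to the
#' target level by the end year, evaluated on the decadal grid; with the
#' default anchors the first non-zero step is 2030.
#'
#' @param spec An \code{fs_scenario}, or a numeric level.
#' @param base_year Ramp anchor with f = 0 (default 2020).
#' @param end_year Year at which f = level.
#' @return A list of class \code{fs_schedule}.
#' @export
substitution_schedule <- function(spec, base_year = 2020, end_year = NULL) {
  if (inherits(spec, "fs_scenario")) {
    level <- spec$level
    if (is.null(end_year)) end_year <- spec$end_year
  } else {
    level <- spec
    if (is.null(end_year)) end_year <- 2050
  }
  structure(list(base_year = base_year, end_year = end_year, level = level),
            class = "fs_schedule")
}

#' Substituted fraction at a given year
#'
#' @param schedule An \code{fs_schedule}.
#' @param year Year (vectorized).
#' @return Fraction(s) in [0, level]; 0 before the base year.
#' @examples
#' substitution_fraction(substitution_schedule(0.5), 2040)  # 1/3
#' @export
substitution_fraction <- function(schedule, year) {
  f <- schedule$level * (year - schedule$base_year) /
    (schedule$end_year - schedule$base_year)
  pmin(pmax(f, 0), schedule$level)
}

# ---- applying the substitution ---------------------------------------------

#' Apply the substitution wedge to REF food demand
#'
#' In in-scope regions, ASF food demand for each substituted product is fixed
#' at \eqn{(1 - f(t))} times its REF-scenario value, and an equal product-mass
#' demand for the corresponding novel alternative is created (one-to-one
#' substitution; the alternatives carry the same regionally differentiated
#' calorie content, so total calories from product + alternative equal the
#' REF ASF calories exactly).  Out-of-scope regions keep endogenous demand.
#'
#' @param ref_food_demand Matrix (regions x commodities) of REF food demand
#'   at the same year.
#' @param spec An \code{fs_scenario}.
#' @param year Year on the decadal grid.
#' @param recipes Named recipe list (used to verify coverage).
#' @param world The \code{fs_world} (for region/commodity names).
#' @return List with \code{asf_food_demand} (matrix regions x commodities,
#'   NA = endogenous) and \code{alt_demand} (matrix regions x substituted
#'   products, product-mass units).
#' @export
apply_substitution <- function(ref_food_demand, spec, year, recipes, world) {
  regs <- rownames(ref_food_demand)
  f <- substitution_fraction(substitution_schedule(spec), year)
  prods <- spec$products
  have <- vapply(recipes, function(r) r$product, "")
  if (!all(prods %in% have)) {
    stop("configuration error: no recipe available for product(s) ",
         paste(setdiff(prods, have), collapse = ", "))
  }
  in_scope <- if (identical(spec$scope, "GLOB")) regs else spec$scope
  fixed <- matrix(NA_real_, length(regs), ncol(ref_food_demand),
                  dimnames = dimnames(ref_food_demand))
  alt <- matrix(0, length(regs), length(prods),
                dimnames = list(regs, prods))
  for (p in prods) {
    fixed[in_scope, p] <- (1 - f) * ref_food_demand[in_scope, p]
    alt[in_scope, p] <- f * ref_food_demand[in_scope, p]
  }
  keep <- colSums(!is.na(fixed)) > 0
  list(asf_food_demand = fixed[, keep, drop = FALSE], alt_demand = alt)
}

#' Import caps under local sourcing
#'
#' Under local sourcing, total crop imports across each macro-region border
#' are capped at their REF-scenario level for the same year (trade within a
#' macro region is not represented, so no further restriction applies);
#' under global sourcing there are no caps.
#'
#' @param spec An \code{fs_scenario}.
#' @param ref_imports Matrix (regions x commodities) of REF imports at the
#'   same year.
#' @param crops Crop identifiers to cap (default the 18 model crops).
#' @return Matrix (regions x crops) of import bounds; \code{Inf} = no cap.
#'   Crops with zero REF imports are forced to zero imports.
#' @export
import_cap_constraints <- function(spec, ref_imports, crops = fs_crops()) {
  if (is.null(ref_imports)) {
    stop("dependency error: REF trade flows are required for import caps")
  }
  regs <- rownames(ref_imports)
  caps <- matrix(Inf, length(regs), length(crops),
                 dimnames = list(regs, crops))
  if (identical(spec$sourcing, "local")) {
    caps[, crops] <- ref_imports[, crops, drop = FALSE]
  }
  caps
}
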