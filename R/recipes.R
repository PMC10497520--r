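# ---- fixtures ---------------------------------------------------------------

.EAA <- c("his", "ile", "leu", "lys", "saa", "aaa", "thr", "trp", "val")

#' Nutrient and amino-acid fixture tables
#'
#' Synthetic (but nutritionally plausible) macronutrient fractions and
#' essential-amino-acid profiles for the recipe ingredients, the adult
#' amino-acid scoring pattern, target macronutrient profiles of the animal
#' products being replaced, and a beef reference amino-acid profile whose
#' Amino Acid Score is 0.94.  Sulphur amino acids (\code{saa}) and aromatic
#' amino acids (\code{aaa}) are scored as groups, the usual convention.
#'
#' @return A list with \code{ingredients} (data frame: protein/fat/carb
#'   fractions), \code{aa} (matrix, mg per g protein), \code{reference_pattern}
#'   (named vector, mg per g protein), \code{animal_targets} and
#'   \code{beef_reference_aa}.
#' @export
default_nutrients <- function() {
  ing <- c("soy_protein_isolate", "soy_protein_concentrate",
           "rapeseed_protein_isolate", "rapeseed_meal",
           "potato_protein_isolate", "wheat_protein_concentrate",
           "wheat_flour", "peanut_flour", "sweet_potato_dried", "cane_syrup",
           "cassava_raw", "chickpea_protein", "beans_dry", "sorghum_flour",
           "vegetable_oil")
  ingredients <- data.frame(
    ingredient = ing,
    protein = c(0.90, 0.65, 0.85, 0.35, 0.85, 0.75, 0.10, 0.50, 0.05, 0.00,
                0.012, 0.60, 0.22, 0.10, 0.00),
    fat = c(0.04, 0.01, 0.03, 0.10, 0.01, 0.02, 0.01, 0.12, 0.01, 0.00,
            0.003, 0.06, 0.01, 0.03, 1.00),
    carbohydrate = c(0.02, 0.20, 0.04, 0.35, 0.05, 0.15, 0.75, 0.30, 0.85,
                     0.80, 0.38, 0.25, 0.60, 0.75, 0.00),
    row.names = ing, stringsAsFactors = FALSE
  )
  aa <- matrix(c(
    26, 49, 82, 63, 26, 90, 38, 13, 50,     # soy protein isolate
    26, 48, 80, 62, 26, 88, 38, 13, 49,     # soy protein concentrate
    29, 42, 72, 55, 40, 70, 42, 13, 52,     # rapeseed protein isolate
    27, 40, 68, 50, 45, 65, 42, 12, 50,     # rapeseed meal
    21, 52, 90, 75, 35, 90, 52, 13, 60,     # potato protein isolate
    21, 38, 70, 15, 35, 80, 25,  9, 42,     # wheat protein concentrate
    22, 35, 68, 22, 40, 78, 27, 11, 42,     # wheat flour
    25, 35, 65, 35, 24, 90, 26, 10, 42,     # peanut flour
    20, 38, 60, 45, 30, 70, 42, 14, 50,     # sweet potato, dried
     0,  0,  0,  0,  0,  0,  0,  0,  0,     # cane syrup (no protein)
    20, 30, 45, 40, 28, 45, 30, 10, 38,     # cassava, raw
    27, 43, 72, 67, 25, 80, 37, 10, 42,     # chickpea protein
    28, 42, 76, 72, 19, 80, 40, 11, 46,     # beans, dry
    22, 38, 140, 21, 30, 85, 31, 10, 48,    # sorghum flour
     0,  0,  0,  0,  0,  0,  0,  0,  0      # vegetable oil
  ), nrow = length(ing), byrow = TRUE, dimnames = list(ing, .EAA))
  pattern <- c(his = 15, ile = 30, leu = 59, lys = 45, saa = 22,
               aaa = 38, thr = 23, trp = 6, val = 39)
  targets <- data.frame(
    product = c("beef", "chicken", "pork", "milk"),
    protein = c(0.19, 0.19, 0.17, 0.034),
    fat = c(0.20, 0.09, 0.21, 0.037),
    carbohydrate = c(0, 0, 0, 0.048),
    row.names = c("beef", "chicken", "pork", "milk"),
    stringsAsFactors = FALSE
  )
  beef_aa <- c(his = 25, ile = 45, leu = 80, lys = 85, saa = 22 * 0.94,
               aaa = 75, thr = 45, trp = 11, val = 48)
  list(ingredients = ingredients, aa = aa, reference_pattern = pattern,
       animal_targets = targets, beef_reference_aa = beef_aa)
}

#' Ingredient-to-primary-crop conversions
#'
#' Conversion yields (t processed ingredient per t primary crop) mapping each
#' recipe ingredient to one of the 18 model crops, plus oil extraction yields
#' per oil crop.  Fixture values in plausible processing ranges.
#'
#' @return List with data frame \code{ingredients} and named vector
#'   \code{oil_yields}.
#' @export
default_conversions <- function() {
  df <- data.frame(
    ingredient = c("soy_protein_isolate", "soy_protein_concentrate",
                   "rapeseed_protein_isolate", "rapeseed_meal",
                   "potato_protein_isolate", "wheat_protein_concentrate",
                   "wheat_flour", "peanut_flour", "sweet_potato_dried",
                   "cane_syrup", "cassava_raw", "chickpea_protein",
                   "beans_dry", "sorghum_flour"),
    primary_crop = c("soybean", "soybean", "rapeseed", "rapeseed", "potato",
                     "wheat", "wheat", "groundnut", "sweet_potato",
                     "sugarcane", "cassava", "chickpea", "dry_beans",
                     "sorghum"),
    conversion_yield = c(0.30, 0.35, 0.25, 0.55, 0.05, 0.10, 0.75, 0.60,
                         0.30, 0.15, 1.00, 0.25, 1.00, 0.80),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$ingredient
  oil <- c(soybean = 0.18, rapeseed = 0.40, sunflower = 0.42,
           oil_palm = 0.20, groundnut = 0.40, cottonseed = 0.15)
  list(ingredients = df, oil_yields = oil)
}

#' Plant-based recipes for the animal products
#'
#' The eleven ingredient-share recipes (five for beef, two each for chicken,
#' pork and milk), read from the packaged recipe table.  The non-itemized
#' remainder of each recipe is water, contributing neither nutrients nor crop
#' demand.
#'
#' @param file Optional path to a recipe CSV (columns \code{recipe_id},
#'   \code{product}, \code{ingredient}, \code{share}, \code{role}).
#' @return Named list of \code{fs_recipe} objects.
#' @export
default_recipes <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "recipes.csv", package = "foodshift")
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(tab$recipe_id)) {
    rows <- tab[tab$recipe_id == id, , drop = FALSE]
    oil <- rows$role == "oil"
    out[[id]] <- recipe(
      id = id, product = rows$product[1],
      ingredients = data.frame(ingredient = rows$ingredient[!oil],
                               share = rows$share[!oil],
                               role = rows$role[!oil],
                               stringsAsFactors = FALSE),
      oil_share = if (any(oil)) sum(rows$share[oil]) else 0)
  }
  out[order(names(out))]
}

#' Construct a recipe
#'
#' @param id Recipe identifier (e.g. \code{"B1"}).
#' @param product Animal product replaced (beef, chicken, pork or milk).
#' @param ingredients Data frame with columns \code{ingredient}, \code{share}
#'   (mass fractions) and \code{role} (\code{protein}/\code{binder}).
#' @param oil_share Mass fraction filled by the region-assigned vegetable oil.
#' @return An \code{fs_recipe}.
#' @export
recipe <- function(id, product, ingredients, oil_share = 0) {
  stopifnot(is.data.frame(ingredients),
            all(c("ingredient", "share") %in% names(ingredients)))
  if (any(ingredients$share < 0) || oil_share < 0) {
    stop("invalid-recipe error: negative ingredient share")
  }
  structure(list(id = id, product = product, ingredients = ingredients,
                 oil_share = oil_share), class = "fs_recipe")
}

# ---- recipe operations ------------------------------------------------------

#' Water share of a recipe
#'
#' The non-itemized remainder of the recipe mass is water:
#' \eqn{1 - \sum_i s_i - s_{oil}}.
#'
#' @param recipe An \code{fs_recipe}.
#' @return Fraction in (0, 1].
#' @export
water_share <- function(recipe) {
  tot <- sum(recipe$ingredients$share) + recipe$oil_share
  if (tot >= 1) {
    stop("invalid-recipe error: ingredient shares sum to ", tot,
         " (must be < 1)")
  }
  1 - tot
}

#' Macronutrient profile of a recipe
#'
#' Mass-weighted sum of ingredient macronutrient fractions (the oil share uses
#' the vegetable-oil profile; water contributes zeros).
#'
#' @param recipe An \code{fs_recipe}.
#' @param nutrients Nutrient tables (default \code{\link{default_nutrients}}).
#' @return Named vector (protein, fat, carbohydrate) per unit product mass.
#' @export
macronutrient_profile <- function(recipe, nutrients = default_nutrients()) {
  tab <- nutrients$ingredients
  ing <- recipe$ingredients$ingredient
  missing <- setdiff(ing, rownames(tab))
  if (length(missing) > 0) {
    stop("lookup error: no nutrient entry for ingredient(s): ",
         paste(missing, collapse = ", "))
  }
  sh <- recipe$ingredients$share
  prof <- c(protein = 0, fat = 0, carbohydrate = 0)
  for (k in seq_along(ing)) {
    prof <- prof + sh[k] * unlist(tab[ing[k], c("protein", "fat",
                                                "carbohydrate")])
  }
  if (recipe$oil_share > 0) {
    prof <- prof + recipe$oil_share *
      unlist(tab["vegetable_oil", c("protein", "fat", "carbohydrate")])
  }
  names(prof) <- c("protein", "fat", "carbohydrate")
  prof
}

#' Amino Acid Score of a recipe
#'
#' AAS is the minimum, over the nine essential amino acids (sulphur and
#' aromatic amino acids scored as groups), of the ratio of the recipe's pooled
#' amino-acid content (mg per g protein) to the scoring pattern, truncated at
#' 1.0.  Not corrected for digestibility.
#'
#' @inheritParams macronutrient_profile
#' @param truncate Truncate the score at 1.0 (default TRUE).
#' @return AAS in [0, 1] (untruncated values may exceed 1 when
#'   \code{truncate = FALSE}).
#' @export
amino_acid_score <- function(recipe, nutrients = default_nutrients(),
                             truncate = TRUE) {
  tab <- nutrients$ingredients
  ing <- recipe$ingredients$ingredient
  missing <- setdiff(ing, rownames(nutrients$aa))
  if (length(missing) > 0) {
    stop("lookup error: no amino-acid profile for ingredient(s): ",
         paste(missing, collapse = ", "))
  }
  sh <- recipe$ingredients$share
  prot <- sh * tab[ing, "protein"]
  if (sum(prot) <= 0) {
    stop("undefined-score error: recipe has zero total protein")
  }
  pooled <- colSums(nutrients$aa[ing, , drop = FALSE] * prot) / sum(prot)
  score <- min(pooled / nutrients$reference_pattern)
  if (truncate) min(score, 1) else score
}

#' Nutritional equivalence check
#'
#' A recipe passes when its macronutrient deviations from the target animal
#' product are within tolerance and its Amino Acid Score reaches the
#' threshold.  The M2 milk recipe is exempt from the AAS threshold (it is
#' assumed to be supplemented with additional amino acids).
#'
#' @inheritParams macronutrient_profile
#' @param target Named vector (protein, fat, carbohydrate) of the replaced
#'   product; default the packaged target for \code{recipe$product}.
#' @param tolerances Named absolute tolerances per macronutrient.
#' @param aas_threshold Minimum AAS (default 0.9).
#' @return List with \code{pass}, \code{deviations}, \code{aas} and
#'   \code{reasons} (character, empty when passing).
#' @export
equivalence_check <- function(recipe, target = NULL,
                              nutrients = default_nutrients(),
                              tolerances = c(protein = 0.05, fat = 0.05,
                                             carbohydrate = 0.15),
                              aas_threshold = 0.9) {
  if (is.null(target)) {
    tt <- nutrients$animal_targets
    if (!recipe$product %in% rownames(tt)) {
      stop("lookup error: no target profile for product ", recipe$product)
    }
    target <- unlist(tt[recipe$product, c("protein", "fat", "carbohydrate")])
    names(target) <- c("protein", "fat", "carbohydrate")
  }
  prof <- macronutrient_profile(recipe, nutrients)
  dev <- prof - target[names(prof)]
  aas <- amino_acid_score(recipe, nutrients)
  reasons <- character()
  over <- abs(dev) > tolerances[names(dev)]
  if (any(over)) {
    reasons <- c(reasons, paste0("macronutrient deviation: ",
                                 paste(names(dev)[over], collapse = ", ")))
  }
  if (aas < aas_threshold && recipe$id != "M2") {
    reasons <- c(reasons, "AAS below threshold")
  }
  list(pass = length(reasons) == 0, deviations = dev, aas = aas,
       reasons = reasons)
}

#' Primary-crop demand of a quantity of novel alternative
#'
#' Converts a product-mass quantity of a recipe into the primary-crop basket
#' it requires.  Under inefficient processing the entire primary commodity
#' needed to produce each processed ingredient is charged (ingredient mass
#' divided by the conversion yield); under efficient processing all
#' by-products find a use and only the ingredient's own weight is charged.
#'
#' @param recipe An \code{fs_recipe}.
#' @param quantity Tonnes (any unit) of alternative product; the basket is
#'   linear in it.
#' @param mode \code{"efficient"} or \code{"inefficient"}.
#' @param conversions Conversion tables (default
#'   \code{\link{default_conversions}}).
#' @param oil Oil crop assigned to the region (one of the six oil crops).
#' @return Named numeric vector over the 18 crops (same unit as
#'   \code{quantity}).
#' @export
primary_crop_demand <- function(recipe, quantity,
                                mode = c("inefficient", "efficient"),
                                conversions = default_conversions(),
                                oil = "soybean") {
  mode <- match.arg(mode)
  if (quantity < 0) stop("domain error: negative quantity")
  basket <- stats::setNames(numeric(length(fs_crops())), fs_crops())
  conv <- conversions$ingredients
  ing <- recipe$ingredients
  for (k in seq_len(nrow(ing))) {
    nm <- ing$ingredient[k]
    if (!nm %in% rownames(conv)) {
      stop("lookup error: no primary-crop conversion for ingredient ", nm)
    }
    mass <- ing$share[k] * quantity
    crop <- conv[nm, "primary_crop"]
    primary <- if (mode == "inefficient") {
      mass / conv[nm, "conversion_yield"]
    } else mass
    basket[crop] <- basket[crop] + primary
  }
  if (recipe$oil_share > 0) {
    if (!oil %in% names(conversions$oil_yields)) {
      stop("lookup error: no oil extraction yield for crop ", oil)
    }
    mass <- recipe$oil_share * quantity
    primary <- if (mode == "inefficient") {
      mass / conversions$oil_yields[[oil]]
    } else mass
    basket[oil] <- basket[oil] + primary
  }
  basket
}

#' Least-cost recipe for a product at given crop prices
#'
#' Selects, among the permissible recipes for a product, the one whose
#' primary-crop basket per tonne of alternative is cheapest at the given
#' prices.  Ties break deterministically by recipe id order.
#'
#' @param product Animal product being replaced.
#' @param prices Named vector of crop prices (USD/t) for the region.
#' @param recipes Named list of \code{fs_recipe} (default the packaged set).
#' @param mode Processing mode, passed to \code{\link{primary_crop_demand}}.
#' @param conversions Conversion tables.
#' @param oil Oil crop assigned to the region.
#' @return The id of the selected recipe.
#' @export
least_cost_recipe <- function(product, prices, recipes = default_recipes(),
                              mode = "inefficient",
                              conversions = default_conversions(),
                              oil = "soybean") {
  cand <- recipes[vapply(recipes, function(r) r$product == product,
                         logical(1))]
  if (length(cand) == 0) {
    stop("configuration error: no permissible recipe for product ", product)
  }
  cand <- cand[order(names(cand))]
  cost <- vapply(cand, function(r) {
    b <- primary_crop_demand(r, 1, mode, conversions, oil)
    sum(b * prices[names(b)])
  }, numeric(1))
  names(cand)[which.min(cost)]   # which.min takes the first (lexicographic)
}

#' Regional vegetable-oil assignment
#'
#' Under global sourcing each region is assigned the oil crop with the
#' largest total availability (production + imports) in the synthetic
#' baseline; under local sourcing, the oil crop with the largest local
#' production.  The assignment is constant over the run.
#'
#' @param world An \code{fs_world} with a solved base state.
#' @param region A macro-region code.
#' @param sourcing \code{"global"} or \code{"local"}.
#' @return An oil-crop identifier.
#' @export
assign_oil <- function(world, region, sourcing = c("global", "local")) {
  sourcing <- match.arg(sourcing)
  if (!region %in% world$config$regions) {
    stop("configuration error: unknown region ", region)
  }
  sol <- world$base_state$solution
  oc <- world$commodities$oil_crops
  avail <- if (sourcing == "global") {
    sol$production[region, oc] + sol$imports[region, oc]
  } else {
    sol$production[region, oc]
  }
  if (all(avail <= 0)) {
    stop("configuration error: region ", region,
         " has zero oil-crop availability under ", sourcing, " sourcing")
  }
  oc[which.max(avail)]
}

#' Oil assignments for every region
#'
#' @param world An \code{fs_world}.
#' @return Data frame (region, sourcing, oil), one row per region and
#'   sourcing mode.
#' @export
oil_assignment_table <- function(world) {
  regs <- world$config$regions
  do.call(rbind, lapply(c("global", "local"), function(s) {
    data.frame(region = regs,
               sourcing = s,
               oil = vapply(regs, function(r) assign_oil(world, r, s), ""),
               stringsAsFactors = FALSE)
  }))
}

# recipe choice and alternative-ingredient crop demand for one step
.choose_recipes <- function(scenario, altq, prices, recipes, world, oil) {
  regs <- rownames(altq)
  crops <- world$commodities$crops
  A <- .mat(regs, crops, 0)
  rows <- list()
  for (p in colnames(altq)) {
    for (r in regs) {
      qty <- altq[r, p]
      if (qty <= 0) next
      id <- if (identical(scenario$recipe_rule, "ENDOGENOUS")) {
        least_cost_recipe(p, prices[r, crops], recipes,
                          mode = scenario$processing,
                          conversions = world$conversions, oil = oil[[r]])
      } else scenario$recipe_rule
      basket <- primary_crop_demand(recipes[[id]], qty,
                                    mode = scenario$processing,
                                    conversions = world$conversions,
                                    oil = oil[[r]])
      A[r, ] <- A[r, ] + basket
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, product = p, recipe = id, quantity = qty,
        stringsAsFactors = FALSE)
    }
  }
  list(crop_demand = A,
       choice = if (length(rows)) do.call(rbind, rows) else NULL)
}
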