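# ---- restoration cohorts ----------------------------------------------------

#' Allocate abandoned agricultural land to restoration cohorts
#'
#' Restoration (afforestation with locally occurring species) takes place
#' only within former forest ecosystems: of the newly abandoned area in each
#' region, the fraction \code{forest_biome_share} is eligible, clamped to the
#' per-region minimum/maximum afforestation bounds and to the abandoned area
#' itself.  Land not allocated stays in the abandoned pool as other natural
#' land without restoration credit.
#'
#' @param abandoned Named vector of newly abandoned area per region (Mha).
#' @param region_profiles Data frame with rownames = regions and columns
#'   \code{forest_biome_share} and \code{climate_zone}.
#' @param bounds List with named vectors \code{min} and \code{max} (Mha per
#'   region and step).
#' @param year Cohort start year.
#' @return List with \code{cohorts} (data frame region, start_year, area,
#'   climate_zone), \code{restored} and \code{unrestored} named vectors.
#' @export
allocate_restoration <- function(abandoned, region_profiles, bounds, year) {
  regs <- names(abandoned)
  if (any(abandoned < -1e-9)) {
    stop("accounting error: negative abandoned area")
  }
  abandoned <- pmax(abandoned, 0)
  bmin <- bounds$min[regs]; bmax <- bounds$max[regs]
  if (any(bmin > bmax)) {
    stop("configuration error: restoration bounds with min > max")
  }
  eligible <- abandoned * region_profiles[regs, "forest_biome_share"]
  restored <- pmin(pmax(eligible, bmin), bmax)
  restored <- pmin(restored, abandoned)      # never exceed the pool
  unrestored <- abandoned - restored
  keep <- restored > 1e-9
  cohorts <- if (any(keep)) {
    data.frame(
      region = regs[keep], start_year = as.integer(year),
      area = unname(restored[keep]),
      climate_zone = region_profiles[regs[keep], "climate_zone"],
      stringsAsFactors = FALSE)
  } else {
    data.frame(region = character(), start_year = integer(),
               area = numeric(), climate_zone = character(),
               stringsAsFactors = FALSE)
  }
  rownames(cohorts) <- NULL
  list(cohorts = cohorts, restored = stats::setNames(restored, regs),
       unrestored = stats::setNames(unrestored, regs))
}

# saturating carbon density curve, t C/ha at stand age tau
.carbon_density <- function(tau, cmax, k) cmax * (1 - exp(-k * pmax(tau, 0)))

#' Carbon sequestration of restoration cohorts
#'
#' Each cohort accrues carbon along a saturating growth curve
#' \eqn{C(\tau) = C_{max}(1 - e^{-k\tau})} for its climate zone.  The annual
#' sink attributed to a report year is
#' \eqn{\sum_i A_i [C(\tau_i + \Delta) - C(\tau_i)]/\Delta \times 44/12} with
#' \eqn{\tau_i} the cohort age at that year and \eqn{\Delta} the step length,
#' reported as a positive sink (enter it as a negative emission in combined
#' ledgers).
#'
#' @param ledger Restoration ledger (list with \code{cohorts}).
#' @param curves List with named vectors \code{cmax} (t C/ha) and \code{k}
#'   (1/yr) per climate zone.
#' @param year Report year.
#' @param step_years Step length Delta (default 10).
#' @param zones Unused placeholder for region-to-zone mapping when cohorts
#'   lack one.
#' @return Named vector, Gt CO2/yr by region (regions with cohorts).
#' @export
sequestration <- function(ledger, curves, year, step_years = 10,
                          zones = NULL) {
  co <- ledger$cohorts
  out <- numeric(0)
  if (is.null(co) || nrow(co) == 0) return(out)
  if (any(co$start_year > year)) {
    stop("bookkeeping error: cohort starts after the report year")
  }
  sink <- vapply(seq_len(nrow(co)), function(i) {
    z <- co$climate_zone[i]
    if (!z %in% names(curves$cmax)) {
      stop("accounting error: no carbon growth curve for climate zone ", z)
    }
    tau <- year - co$start_year[i]
    dC <- .carbon_density(tau + step_years, curves$cmax[[z]], curves$k[[z]]) -
      .carbon_density(tau, curves$cmax[[z]], curves$k[[z]])
    co$area[i] * dC / step_years * 44 / 12 / 1000   # Mha*tC/ha -> Gt CO2
  }, numeric(1))
  tapply(sink, co$region, sum)
}

# ---- biodiversity intactness ------------------------------------------------

# recovery curve of restored cohorts: piecewise linear from the abandoned
# (other-natural) coefficient to the secondary-forest ceiling
.bii_recovery <- function(tau, start, ceiling, horizon) {
  start + (ceiling - start) * pmin(pmax(tau, 0) / horizon, 1)
}

#' Biodiversity Intactness Index
#'
#' Area-weighted mean of land-class intactness coefficients (primary
#' vegetation = 1), with restored cohorts contributing along a monotone
#' recovery curve from the abandoned-land coefficient toward a
#' secondary-forest ceiling.
#'
#' @param land Matrix (regions x land classes) of areas (Mha); must include
#'   a \code{restored} column consistent with the ledger's cohorts.
#' @param ledger Restoration ledger (list with \code{cohorts}), or NULL when
#'   there are none.
#' @param model List with \code{coef} (named intactness coefficients in
#'   [0,1]), \code{ceiling} and \code{recovery_years}.
#' @param year Report year (sets cohort ages).
#' @return List with \code{by_region} (named vector) and \code{global}
#'   (area-weighted mean).
#' @export
compute_bii <- function(land, ledger, model, year) {
  regs <- rownames(land)
  classes <- colnames(land)
  known <- c(names(model$coef), "restored")
  if (!all(classes %in% known)) {
    stop("accounting error: no intactness coefficient for class ",
         paste(setdiff(classes, known), collapse = ", "))
  }
  if (any(land < -1e-6)) stop("accounting error: negative land area")
  co <- if (is.null(ledger)) NULL else ledger$cohorts
  if ("restored" %in% classes) {
    tot <- stats::setNames(numeric(length(regs)), regs)
    if (!is.null(co) && nrow(co) > 0) {
      s <- tapply(co$area, co$region, sum)
      tot[names(s)] <- s
    }
    if (any(abs(tot - land[, "restored"]) >
            pmax(1e-6, 1e-6 * land[, "restored"]))) {
      stop("accounting error: restored area inconsistent with cohort ledger")
    }
  }
  score <- stats::setNames(numeric(length(regs)), regs)
  for (r in regs) {
    tot_area <- sum(land[r, ])
    if (tot_area <= 0) { score[r] <- NA_real_; next }
    acc <- 0
    for (cl in classes) {
      if (cl == "restored") next
      acc <- acc + land[r, cl] * model$coef[[cl]]
    }
    if ("restored" %in% classes && !is.null(co) && nrow(co) > 0) {
      ci <- co[co$region == r, , drop = FALSE]
      if (nrow(ci) > 0) {
        rc <- .bii_recovery(year - ci$start_year, model$coef[["restored"]],
                            model$ceiling, model$recovery_years)
        acc <- acc + sum(ci$area * rc)
      }
    }
    score[r] <- acc / tot_area
  }
  w <- rowSums(land)
  list(by_region = score,
       global = sum(score * w, na.rm = TRUE) / sum(w[!is.na(score)]))
}
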