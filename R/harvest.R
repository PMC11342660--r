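#' Harvest partition parameters
#'
#' Fixed fractions partitioning the woody carbon of cut or killed trees.
#' 65% of woody biomass is stem material, of which 90% is removed in a fresh
#' cutting ("harvest efficiency") but only 75% in a salvage operation; 13% of
#' woody biomass is branches, of which 40% are removed and burned; the
#' remainder (coarse roots etc.) is left to decay on site. In salvage
#' operations 20% of the affected trees are left untouched. Trees younger
#' than `firewood_age_threshold` (20 yr) are used entirely as firewood.
#'
#' @param stem_fraction stem share of woody biomass.
#' @param harvest_efficiency removed share of stem material, fresh cuttings.
#' @param salvage_efficiency removed share of stem material, salvage.
#' @param branch_fraction branch share of woody biomass.
#' @param branch_removed_burned burned share of branches.
#' @param salvage_trees_left share of killed trees left on site in salvage.
#' @param firewood_age_threshold age (yr) below which cut trees become
#'   firewood entirely.
#' @return list of class `harvest_params`.
#' @export
harvest_params <- function(stem_fraction = 0.65,
                           harvest_efficiency = 0.90,
                           salvage_efficiency = 0.75,
                           branch_fraction = 0.13,
                           branch_removed_burned = 0.40,
                           salvage_trees_left = 0.20,
                           firewood_age_threshold = 20) {
  p <- list(stem_fraction = stem_fraction,
            harvest_efficiency = harvest_efficiency,
            salvage_efficiency = salvage_efficiency,
            branch_fraction = branch_fraction,
            branch_removed_burned = branch_removed_burned,
            salvage_trees_left = salvage_trees_left,
            firewood_age_threshold = firewood_age_threshold)
  fr <- unlist(p[setdiff(names(p), "firewood_age_threshold")])
  if (any(fr < 0 | fr > 1)) stop("harvest fractions must lie in [0, 1]")
  if (stem_fraction + branch_fraction > 1)
    stop("stem_fraction + branch_fraction must not exceed 1")
  class(p) <- "harvest_params"
  p
}

new_harvest_event <- function(year, removed_stem, firewood, residue, source) {
  structure(list(year = year, removed_stem = removed_stem,
                 firewood = firewood, residue = residue, source = source),
            class = "harvest_event")
}

#' Partition the carbon of a fresh cutting
#'
#' For cohorts at or above the firewood age threshold, `0.65 * 0.90` of the
#' cut biomass is removed stem wood (to product allocation), `0.13 * 0.40`
#' is burned as firewood (branches), and the rest — unremoved stem, the
#' remaining branches, and coarse roots — stays on site as residue (to
#' deadwood). Cohorts below the threshold contribute their whole cut biomass
#' to firewood. Residue is computed by difference, so the event closes
#' exactly: `removed_stem + firewood + residue == sum(biomass)`.
#'
#' @param biomass cut carbon per cohort, kgC/m2 (nonnegative).
#' @param age cohort ages (yr), same length as `biomass`.
#' @param params a [harvest_params()] object.
#' @param year calendar year stamped on the event.
#' @return a `harvest_event` with fields `removed_stem`, `firewood`,
#'   `residue`, `source = "fresh"`.
#' @export
#' @examples
#' partition_fresh(1, 50)  # removed 0.585, firewood 0.052, residue 0.363
partition_fresh <- function(biomass, age, params = harvest_params(),
                            year = NA_integer_) {
  stopifnot(length(biomass) == length(age))
  if (any(biomass < 0)) stop("cut biomass must be nonnegative")
  young <- age < params$firewood_age_threshold
  b_old <- sum(biomass[!young])
  removed <- b_old * params$stem_fraction * params$harvest_efficiency
  firewood <- b_old * params$branch_fraction * params$branch_removed_burned +
    sum(biomass[young])
  residue <- sum(biomass) - removed - firewood
  new_harvest_event(year, removed, firewood, residue, "fresh")
}

#' Partition the carbon of a salvage operation after a disturbance
#'
#' 20% of the killed trees are left on site untouched; the processed 80%
#' share follows the fresh-cutting rules but with the reduced salvage
#' efficiency (75% of stem material removed instead of 90%). Salvaged wood
#' follows the same downstream usage patterns as fresh wood. Everything not
#' removed or burned — including the unprocessed share — becomes residue
#' routed to the deadwood pool.
#'
#' @inheritParams partition_fresh
#' @return a `harvest_event` with `source = "salvage"`.
#' @export
#' @examples
#' partition_salvage(1, 50)$removed_stem  # 0.8 * 0.65 * 0.75 = 0.39
partition_salvage <- function(biomass, age, params = harvest_params(),
                              year = NA_integer_) {
  stopifnot(length(biomass) == length(age))
  if (any(biomass < 0)) stop("killed biomass must be nonnegative")
  proc <- (1 - params$salvage_trees_left) * biomass
  young <- age < params$firewood_age_threshold
  b_old <- sum(proc[!young])
  removed <- b_old * params$stem_fraction * params$salvage_efficiency
  firewood <- b_old * params$branch_fraction * params$branch_removed_burned +
    sum(proc[young])
  residue <- sum(biomass) - removed - firewood
  new_harvest_event(year, removed, firewood, residue, "salvage")
}

#' @export
print.harvest_event <- function(x, ...) {
  cat(sprintf("<harvest_event %s year=%s> removed_stem=%.4g firewood=%.4g residue=%.4g kgC/m2\n",
              x$source, x$year, x$removed_stem, x$firewood, x$residue))
  invisible(x)
}
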