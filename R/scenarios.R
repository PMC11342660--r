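#' Default factor levels of the factorial design
#'
#' The nine experimental factors and their levels: climate pathway,
#' disturbance-probability response to warming, initial forest age and type,
#' harvest-intensity multiplier (of the 24% baseline thinning), salvage
#' logging, material-usage and cascade multipliers, and the decarbonization
#' pace (fraction of today's displacement factors remaining in 2050). The
#' full cross-product has 3 * 3 * 2 * 2 * 4 * 2 * 2 * 2 * 3 = 3456 cells.
#'
#' @return named list of level vectors, in design order.
#' @export
scenario_factor_levels <- function() {
  list(
    rcp                  = c("RCP2.6", "RCP4.5", "RCP8.5"),
    disturbance_response = c("constant", "linear", "exponential"),
    forest_age           = c("mature", "young"),
    forest_type          = c("BD", "NE"),
    harvest_intensity    = c(0, 0.5, 1, 1.5),
    salvage              = c(TRUE, FALSE),
    material_usage       = c(1, 1.5),
    cascade              = c(1, 1.5),
    decarb_2050          = c(0.25, 0.5, 0.75)
  )
}

#' Enumerate the full factorial scenario design
#'
#' Builds the cross-product of the supplied factor levels in deterministic
#' lexicographic order: factors in list order, levels in listed order, with
#' the last factor varying fastest. Each scenario carries a `scenario_id`
#' (its 1-based index) and a reproducible `seed_base` derived from it.
#'
#' @param levels named list of level vectors, as [scenario_factor_levels()].
#' @return a `data.frame` of class `scenario_design`, one row per scenario.
#' @export
#' @examples
#' nrow(enumerate_scenarios())  # 3456
enumerate_scenarios <- function(levels = scenario_factor_levels()) {
  if (!length(levels) || is.null(names(levels)) || any(!nzchar(names(levels))))
    stop_config("factor levels must be a non-empty named list")
  for (f in names(levels)) {
    if (!length(levels[[f]]))
      stop_config("factor '", f, "' has no levels")
    if (anyDuplicated(levels[[f]]))
      stop_config("duplicate level within factor '", f, "'")
  }
  grid <- expand.grid(rev(levels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  rownames(grid) <- NULL
  design <- cbind(scenario_id = seq_len(nrow(grid)), grid)
  design$seed_base <- vapply(design$scenario_id, function(i)
    derive_seed(i, "scenario"), integer(1))
  class(design) <- c("scenario_design", "data.frame")
  design
}

#' Generate a synthetic annual temperature-anomaly trajectory
#'
#' Emulates regional climate forcing as an annual mean-temperature anomaly
#' relative to a 1951-1980-style baseline: zero before `ramp_start`, then a
#' quadratic warming ramp reaching the pathway's end-of-century anomaly at
#' `ramp_end`, plus seeded Gaussian interannual noise. The noise realization
#' is derived from `(site_id, seed)` only, so trajectories for different
#' pathways at the same site share weather noise (common random numbers) and
#' identical `(rcp, site_id, seed)` calls return identical series.
#'
#' @param rcp pathway label; must name an element of `end_anomaly`.
#' @param site_id site label (sites are exchangeable stochastic replicates).
#' @param seed integer base seed.
#' @param years simulation years (annual, default 1920-2100).
#' @param end_anomaly named vector of year-`ramp_end` mean anomalies, degC.
#' @param noise_sd interannual noise standard deviation, degC.
#' @param ramp_start,ramp_end calendar years bounding the warming ramp.
#' @return `data.frame` of class `climate_trajectory` with columns `year`,
#'   `dT`; attributes `rcp`, `site_id`.
#' @export
#' @examples
#' cl <- generate_climate("RCP4.5", noise_sd = 0)
#' cl$dT[cl$year == 2100]  # 2.5
generate_climate <- function(rcp, site_id = "site1", seed = 1L,
                             years = 1920:2100,
                             end_anomaly = c("RCP2.6" = 1.0, "RCP4.5" = 2.5,
                                             "RCP8.5" = 4.5),
                             noise_sd = 0.4,
                             ramp_start = 1980, ramp_end = 2100) {
  if (!is.character(rcp) || length(rcp) != 1L || !rcp %in% names(end_anomaly))
    stop_config("unknown rcp label: ", paste(rcp, collapse = ", "))
  frac <- clamp((years - ramp_start) / (ramp_end - ramp_start), 0, 1)
  dT <- end_anomaly[[rcp]] * frac^2
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, site_id, "climate"),
                       stats::rnorm(length(years), 0, noise_sd))
    dT <- dT + noise
  }
  out <- data.frame(year = years, dT = as.numeric(dT))
  attr(out, "rcp") <- rcp
  attr(out, "site_id") <- site_id
  class(out) <- c("climate_trajectory", "data.frame")
  out
}

#' Scale a baseline disturbance probability with the temperature anomaly
#'
#' Annual per-patch probability of a stand-replacing disturbance as a
#' function of the warming anomaly: `constant` keeps the baseline
#' `p0 = 1/return-interval`; `linear` applies `p0 * (1 + beta * max(dT, 0))`;
#' `exponential` applies `p0 * 2^(max(dT, 0) / doubling)` (a doubling of the
#' disturbance rate per `doubling` degC of warming). Cooling anomalies never
#' reduce the probability below `p0`, and the result is clamped to `[0, 1]`.
#'
#' @param p0 baseline annual probability, in (0, 1).
#' @param dT temperature anomaly (degC); vectorized.
#' @param response one of `"constant"`, `"linear"`, `"exponential"`.
#' @param beta linear slope per degC (default 1).
#' @param doubling exponential doubling temperature, degC (default 1).
#' @return probability vector, same length as `dT`.
#' @export
#' @examples
#' disturbance_probability(1 / 300, 1, "exponential")  # 1/150
disturbance_probability <- function(p0, dT, response,
                                    beta = 1, doubling = 1) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("p0 must be a single probability in (0, 1)")
  if (any(!is.finite(dT))) stop("dT must be finite")
  w <- pmax(dT, 0)
  p <- switch(as.character(response),
    constant    = rep(p0, length(w)),
    linear      = p0 * (1 + beta * w),
    exponential = p0 * 2^(w / doubling),
    stop_config("unknown disturbance response label: ", response)
  )
  clamp(p, 0, 1)
}

#' Annual disturbance-probability schedule for a climate trajectory
#'
#' @param p0 baseline annual probability (1/return-interval).
#' @param climate a [generate_climate()] trajectory.
#' @param response disturbance response label.
#' @param ... passed to [disturbance_probability()].
#' @return `data.frame` of class `disturbance_schedule` with `year`, `p`;
#'   attributes `p0`, `response`.
#' @export
disturbance_schedule <- function(p0, climate, response, ...) {
  out <- data.frame(year = climate$year,
                    p = disturbance_probability(p0, climate$dT, response, ...))
  attr(out, "p0") <- p0
  attr(out, "response") <- response
  class(out) <- c("disturbance_schedule", "data.frame")
  out
}
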