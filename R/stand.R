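#' Stand-dynamics emulator parameters
#'
#' Constants of the reduced-form cohort model standing in for a full
#' process-based vegetation model. Woody stand growth is logistic:
#' `NPP = npp_max * max(0, 1 - B/K) * max(0, 1 + a*dT - b*dT^2)`, where `B`
#' is total vegetation carbon, `K` the carrying capacity and `dT` the
#' warming anomaly. Background mortality transfers a fixed biomass fraction
#' to deadwood each year; deadwood and soil decay at first-order rates with
#' Q10 temperature sensitivity, a fixed humified share of deadwood decay
#' entering the soil pool. Harvest interval and the disturbance return
#' interval are forest-type specific (needle-leaved: 20 yr thinning cycle,
#' 300 yr disturbance return; broad-leaved: 25 yr and 1000 yr).
#'
#' @param forest_type `"NE"` (needle-leaved evergreen) or `"BD"`
#'   (broad-leaved deciduous); sets interval defaults.
#' @param n_patches number of replicate patches (default 100).
#' @param npp_max potential annual woody carbon gain at zero standing stock,
#'   kgC/m2/yr (default 0.714, the regional NPP calibration anchor).
#' @param carrying_capacity vegetation carbon asymptote K, kgC/m2.
#' @param background_mortality fraction of live biomass dying per year.
#' @param harvest_interval years between partial harvests (NULL = by type).
#' @param harvest_fraction baseline fraction of each cohort cut per event.
#' @param disturbance_interval baseline disturbance return interval, years
#'   (NULL = by type); the annual probability is its reciprocal.
#' @param climate_growth_a,climate_growth_b coefficients of the growth
#'   modifier `1 + a*dT - b*dT^2` (positive CO2/growing-season effects at
#'   moderate warming, drought/heat penalties beyond).
#' @param deadwood_k,soil_k base decay rates of the dead pools, /yr.
#' @param humification share of deadwood decay routed to the soil pool.
#' @param q10 temperature sensitivity of dead-pool decay.
#' @param seedling_mass floor weight (kgC/m2) a zero-biomass regeneration
#'   cohort carries in the NPP allocation, so establishment can proceed in a
#'   non-empty stand.
#' @param harvest a [harvest_params()] object.
#' @return list of class `stand_params`.
#' @export
stand_params <- function(forest_type = c("NE", "BD"),
                         n_patches = 100L,
                         npp_max = 0.714,
                         carrying_capacity = 18,
                         background_mortality = 0.01,
                         harvest_interval = NULL,
                         harvest_fraction = 0.24,
                         disturbance_interval = NULL,
                         climate_growth_a = 0.05,
                         climate_growth_b = 0.01,
                         deadwood_k = 0.04,
                         humification = 0.3,
                         soil_k = 0.01,
                         q10 = 2,
                         seedling_mass = 0.05,
                         harvest = harvest_params()) {
  forest_type <- match.arg(forest_type)
  if (is.null(harvest_interval))
    harvest_interval <- if (forest_type == "NE") 20L else 25L
  if (is.null(disturbance_interval))
    disturbance_interval <- if (forest_type == "NE") 300 else 1000
  rates <- c(background_mortality, harvest_fraction, deadwood_k,
             humification, soil_k)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (harvest_interval < 1 || disturbance_interval < 1)
    stop("intervals must be positive")
  structure(list(forest_type = forest_type,
                 n_patches = as.integer(n_patches),
                 npp_max = npp_max,
                 carrying_capacity = carrying_capacity,
                 background_mortality = background_mortality,
                 harvest_interval = as.integer(harvest_interval),
                 harvest_fraction = harvest_fraction,
                 disturbance_interval = disturbance_interval,
                 climate_growth_a = climate_growth_a,
                 climate_growth_b = climate_growth_b,
                 deadwood_k = deadwood_k,
                 humification = humification,
                 soil_k = soil_k,
                 q10 = q10,
                 seedling_mass = seedling_mass,
                 harvest = harvest),
            class = "stand_params")
}

planting_window <- function(forest_age) {
  switch(as.character(forest_age),
         mature = 1921:1940,
         young  = 1981:2000,
         stop_config("unknown forest age label: ", forest_age))
}

#' Initialize the replicate patches of a stand
#'
#' Each patch receives one (initially zero-biomass) cohort per planting year
#' of the age class window — 1921-1940 for mature, 1981-2000 for young
#' stands — and a harvest phase offset drawn uniformly in
#' `[0, harvest_interval)` from the seed, so cuttings are staggered across
#' patches. Cohorts become active (receive growth) once the simulation
#' reaches their establishment year.
#'
#' @param forest_age `"mature"` or `"young"` (a scenario list with a
#'   `forest_age` field is also accepted).
#' @param params a [stand_params()] object.
#' @param seed integer base seed.
#' @param site_id site label; phases are derived from `(seed, site_id)` only,
#'   independent of scenario factors.
#' @return list of class `stand_state`: `patches` (each with `est`, `bio`,
#'   `deadwood`, `soil`, `phase`) plus the age label.
#' @export
initialize_stand <- function(forest_age, params = stand_params(),
                             seed = 1L, site_id = "site1") {
  if (is.list(forest_age)) forest_age <- forest_age$forest_age
  plant <- planting_window(forest_age)
  u <- with_seed(derive_seed(seed, site_id, "phase"),
                 stats::runif(params$n_patches))
  phases <- floor(u * params$harvest_interval)
  patches <- lapply(seq_len(params$n_patches), function(i) {
    list(est = as.numeric(plant),
         bio = numeric(length(plant)),
         deadwood = 0, soil = 0,
         phase = phases[i])
  })
  structure(list(patches = patches, forest_age = forest_age),
            class = "stand_state")
}

#' One year of growth and background mortality for a patch
#'
#' Stand-level NPP follows the logistic form with the climate growth
#' modifier (floored at zero), allocated across established cohorts with
#' weights `max(biomass, seedling_mass)` — proportional to biomass for grown
#' cohorts while letting freshly established zero-biomass cohorts enter.
#' Background mortality then moves a fixed fraction of live biomass to the
#' deadwood pool.
#'
#' @param patch a patch element of a [initialize_stand()] state.
#' @param dT temperature anomaly, degC.
#' @param params a [stand_params()] object.
#' @param year current simulation year.
#' @return list: updated `patch`, `npp` and `mortality` fluxes (kgC/m2/yr).
#' @export
annual_growth <- function(patch, dT, params, year) {
  active <- patch$est <= year
  npp <- 0
  if (any(active)) {
    B <- sum(patch$bio[active])
    modifier <- max(0, 1 + params$climate_growth_a * dT -
                       params$climate_growth_b * dT^2)
    npp <- params$npp_max * max(0, 1 - B / params$carrying_capacity) * modifier
    if (npp > 0) {
      w <- pmax(patch$bio[active], params$seedling_mass)
      patch$bio[active] <- patch$bio[active] + npp * (w / sum(w))
    }
  }
  dead <- params$background_mortality * patch$bio
  patch$bio <- patch$bio - dead
  mortality <- sum(dead)
  patch$deadwood <- patch$deadwood + mortality
  list(patch = patch, npp = npp, mortality = mortality)
}

#' Stochastic stand-replacing disturbance draw for a patch
#'
#' The patch is struck iff the shared annual uniform draw `u` falls below
#' the year's disturbance probability `p` (so, under a shared draw sequence,
#' the event set of a lower-probability schedule is a subset of a higher
#' one). An event kills all established cohorts; the killed biomass is
#' returned for routing (salvage or deadwood) by the caller, and a single
#' zero-biomass regeneration cohort establishes the following year.
#'
#' @param patch a patch state.
#' @param u uniform draw in `[0, 1)`.
#' @param p annual disturbance probability.
#' @param year current simulation year.
#' @return list: updated `patch`, and `killed` (list with `biomass`, `age`
#'   vectors) or `NULL` if no event struck an established stand.
#' @export
disturbance_step <- function(patch, u, p, year) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("disturbance probability outside [0, 1]")
  active <- patch$est <= year
  if (u >= p || !any(active)) return(list(patch = patch, killed = NULL))
  killed <- list(biomass = patch$bio[active], age = year - patch$est[active])
  patch$est <- year + 1
  patch$bio <- 0
  list(patch = patch, killed = killed)
}

#' Scheduled partial harvest of a patch
#'
#' Fires in years with `(year - phase) %% harvest_interval == 0`, removing
#' the effective fraction `harvest_fraction * multiplier` of every
#' established cohort's biomass, where the multiplier is 1 until 2020 and
#' the scenario's harvest-intensity level afterwards. The cut carbon is
#' partitioned by [partition_fresh()] (cohorts younger than 20 yr go
#' entirely to firewood) and a regeneration cohort establishes next year.
#'
#' @param patch a patch state.
#' @param year current simulation year.
#' @param scenario list with at least `harvest_intensity`.
#' @param params a [stand_params()] object.
#' @return list: updated `patch`, and `event` (a `harvest_event`) or `NULL`.
#' @export
scheduled_harvest <- function(patch, year, scenario, params) {
  if ((year - patch$phase) %% params$harvest_interval != 0)
    return(list(patch = patch, event = NULL))
  mult <- if (year > 2020) scenario$harvest_intensity else 1
  f <- params$harvest_fraction * mult
  active <- patch$est <= year & patch$bio > 0
  if (f <= 0 || !any(active)) return(list(patch = patch, event = NULL))
  cut <- f * patch$bio[active]
  ev <- partition_fresh(cut, year - patch$est[active], params$harvest, year)
  patch$bio[active] <- patch$bio[active] - cut
  if (!any(patch$est == year + 1)) {
    patch$est <- c(patch$est, year + 1)
    patch$bio <- c(patch$bio, 0)
  }
  list(patch = patch, event = ev)
}

#' Annual decay of the deadwood and soil pools
#'
#' Deadwood loses the fraction `deadwood_k * q10^(dT/10)` (clamped to at
#' most 1); the humified share of that loss enters the soil pool, the rest
#' is respired. Soil loses `soil_k * q10^(dT/10)` to the atmosphere.
#'
#' @param patch a patch state.
#' @param dT temperature anomaly, degC.
#' @param params a [stand_params()] object.
#' @return list: updated `patch`, `deadwood_resp`, `soil_resp` (kgC/m2/yr).
#' @export
decay_dead_pools <- function(patch, dT, params) {
  scal <- params$q10^(dT / 10)
  loss <- min(1, params$deadwood_k * scal) * patch$deadwood
  to_soil <- params$humification * loss
  deadwood_resp <- loss - to_soil
  # parallel update: soil respiration acts on the pre-existing soil stock,
  # humified input enters afterwards
  soil_resp <- min(1, params$soil_k * scal) * patch$soil
  patch$deadwood <- patch$deadwood - loss
  patch$soil <- patch$soil - soil_resp + to_soil
  list(patch = patch, deadwood_resp = deadwood_resp, soil_resp = soil_resp)
}

#' Simulate a stand through the full period
#'
#' Runs the per-patch annual sequence growth -> background mortality ->
#' disturbance draw (with optional salvage logging after 2020) -> scheduled
#' harvest -> dead-pool decay over the climate trajectory's years, and
#' returns patch-mean annual pools and fluxes. Disturbance uniforms and
#' harvest phases are derived from `(seed, site_id)` only, independent of
#' scenario factors, so partner scenarios share their stochastic draws
#' (common random numbers) and higher disturbance probabilities produce
#' event supersets.
#'
#' The returned series satisfies, every year, the stand-side carbon closure
#' `diff(veg + deadwood + soil) = npp - removed_stem - firewood -
#' deadwood_resp - soil_resp` to numerical precision.
#'
#' @param scenario list (or `scenario_design` row) with `forest_age`,
#'   `forest_type`, `harvest_intensity`, `salvage`, `disturbance_response`.
#' @param climate a [generate_climate()] trajectory covering the simulation.
#' @param params a [stand_params()] object (defaults to the scenario's type).
#' @param seed integer base seed.
#' @param site_id site label (defaults to the climate's).
#' @return `data.frame` of class `stand_series`: `year`, pools `veg_c`,
#'   `deadwood_c`, `soil_c` (kgC/m2, patch means), fluxes `npp`,
#'   `mortality`, `disturbance_kill`, `removed_stem`, `firewood`,
#'   `residue`, `deadwood_resp`, `soil_resp` (kgC/m2/yr, patch means), and
#'   `disturbance_events` (raw event count across patches).
#' @export
simulate_stand <- function(scenario, climate,
                           params = stand_params(scenario$forest_type),
                           seed = 1L,
                           site_id = attr(climate, "site_id")) {
  scenario <- as.list(scenario)
  if (is.null(site_id)) site_id <- "site1"
  years <- climate$year
  if (any(diff(years) != 1))
    stop("climate trajectory must cover consecutive simulation years")
  ny <- length(years)
  np <- params$n_patches
  p_series <- disturbance_probability(1 / params$disturbance_interval,
                                      climate$dT,
                                      scenario$disturbance_response)
  u <- with_seed(derive_seed(seed, site_id, "disturbance"),
                 matrix(stats::runif(ny * np), nrow = ny, ncol = np))
  state <- initialize_stand(scenario$forest_age, params, seed, site_id)
  patches <- state$patches

  flux_names <- c("npp", "mortality", "disturbance_kill", "removed_stem",
                  "firewood", "residue", "deadwood_resp", "soil_resp")
  fl <- matrix(0, nrow = ny, ncol = length(flux_names),
               dimnames = list(NULL, flux_names))
  pools <- matrix(0, nrow = ny, ncol = 3,
                  dimnames = list(NULL, c("veg_c", "deadwood_c", "soil_c")))
  events <- integer(ny)
  salvage_on <- isTRUE(scenario$salvage) || identical(scenario$salvage, "TRUE")

  for (t in seq_len(ny)) {
    year <- years[t]
    dT <- climate$dT[t]
    p <- p_series[t]
    for (i in seq_len(np)) {
      patch <- patches[[i]]

      g <- annual_growth(patch, dT, params, year)
      patch <- g$patch
      fl[t, "npp"] <- fl[t, "npp"] + g$npp
      fl[t, "mortality"] <- fl[t, "mortality"] + g$mortality

      d <- disturbance_step(patch, u[t, i], p, year)
      patch <- d$patch
      if (!is.null(d$killed)) {
        events[t] <- events[t] + 1L
        kill <- sum(d$killed$biomass)
        fl[t, "disturbance_kill"] <- fl[t, "disturbance_kill"] + kill
        if (salvage_on && year > 2020) {
          ev <- partition_salvage(d$killed$biomass, d$killed$age,
                                  params$harvest, year)
          fl[t, "removed_stem"] <- fl[t, "removed_stem"] + ev$removed_stem
          fl[t, "firewood"] <- fl[t, "firewood"] + ev$firewood
          fl[t, "residue"] <- fl[t, "residue"] + ev$residue
          patch$deadwood <- patch$deadwood + ev$residue
        } else {
          patch$deadwood <- patch$deadwood + kill
        }
      }

      h <- scheduled_harvest(patch, year, scenario, params)
      patch <- h$patch
      if (!is.null(h$event)) {
        ev <- h$event
        fl[t, "removed_stem"] <- fl[t, "removed_stem"] + ev$removed_stem
        fl[t, "firewood"] <- fl[t, "firewood"] + ev$firewood
        fl[t, "residue"] <- fl[t, "residue"] + ev$residue
        patch$deadwood <- patch$deadwood + ev$residue
      }

      dd <- decay_dead_pools(patch, dT, params)
      patch <- dd$patch
      fl[t, "deadwood_resp"] <- fl[t, "deadwood_resp"] + dd$deadwood_resp
      fl[t, "soil_resp"] <- fl[t, "soil_resp"] + dd$soil_resp

      pools[t, 1] <- pools[t, 1] + sum(patch$bio)
      pools[t, 2] <- pools[t, 2] + patch$deadwood
      pools[t, 3] <- pools[t, 3] + patch$soil
      patches[[i]] <- patch
    }
  }

  out <- data.frame(year = years, pools / np, fl / np,
                    disturbance_events = events)
  attr(out, "scenario") <- scenario[c("forest_age", "forest_type",
                                      "harvest_intensity", "salvage",
                                      "disturbance_response")]
  attr(out, "site_id") <- site_id
  class(out) <- c("stand_series", "data.frame")
  out
}
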