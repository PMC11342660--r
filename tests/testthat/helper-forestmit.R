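# Shared fixtures: built in code at test time, nothing stored on disk.

# A constant-climate (dT = 0) trajectory for analytic checks.
flat_climate <- function(years = 1920:2100) {
  cl <- generate_climate("RCP4.5", noise_sd = 0, years = years)
  cl$dT <- rep(0, length(years))
  cl
}

# Baseline default scenario as a plain list.
default_scenario <- function(...) {
  utils::modifyList(list(forest_age = "mature", forest_type = "NE",
                         harvest_intensity = 1, salvage = FALSE,
                         disturbance_response = "exponential"),
                    list(...))
}

# Reduced ensemble shared by the experiment and acceptance tests:
# exponential subset, 10 patches. Computed once per test run.
exp_subset_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lv <- scenario_factor_levels()
      lv$disturbance_response <- "exponential"
      cache <<- run_experiment(lv, n_patches = 10, seed = 1)
    }
    cache
  }
})

# Synthetic results table over the full 3456-cell design: metrics are a
# deterministic function of the factor levels, so pairing arithmetic can be
# verified without running the simulator.
synthetic_results <- function() {
  design <- enumerate_scenarios()
  rows <- lapply(c(2050, 2100), function(h) {
    data.frame(scenario_id = design$scenario_id,
               design[, setdiff(names(design), c("scenario_id", "seed_base"))],
               horizon = h,
               combined_sink = design$harvest_intensity +
                 (design$forest_age == "young") + h / 1000,
               cumulative_avoided = design$material_usage * h / 100,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$total_mitigation <- out$combined_sink + out$cumulative_avoided
  out
}
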