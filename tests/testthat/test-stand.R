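test_that("stand initialization plants the age-class window on every patch", {
  p <- stand_params("NE", n_patches = 3)
  st <- initialize_stand("mature", p, seed = 1)
  expect_length(st$patches, 3)
  for (patch in st$patches) {
    expect_identical(patch$est, as.numeric(1921:1940))
    expect_true(all(patch$bio == 0))
    expect_true(patch$phase >= 0 && patch$phase < p$harvest_interval)
  }
  yb <- initialize_stand("young", stand_params("BD", n_patches = 1), seed = 1)
  expect_length(yb$patches, 1)
  expect_identical(yb$patches[[1]]$est, as.numeric(1981:2000))
  expect_error(initialize_stand("ancient", p), class = "forestmit_config_error")
})

test_that("annual growth follows the logistic form with the climate modifier", {
  p <- stand_params("NE", n_patches = 1)
  patch <- list(est = 1950, bio = p$carrying_capacity, deadwood = 0, soil = 0,
                phase = 0)
  expect_equal(annual_growth(patch, 0, p, 2000)$npp, 0)  # saturation
  # bare stand with one new cohort receives the full potential gain
  bare <- list(est = 2000, bio = 0, deadwood = 0, soil = 0, phase = 0)
  g <- annual_growth(bare, 0, p, 2000)
  expect_equal(g$npp, p$npp_max)
  expect_equal(sum(g$patch$bio), p$npp_max * (1 - p$background_mortality))
  # modifier 1 + 0.05*5 - 0.01*25 = 1 at dT = 5
  g5 <- annual_growth(bare, 5, p, 2000)
  expect_equal(g5$npp, p$npp_max)
  # mortality routed to deadwood
  expect_equal(g$mortality, p$background_mortality * p$npp_max)
  expect_equal(g$patch$deadwood, g$mortality)
})

test_that("disturbance draw kills established cohorts and schedules regeneration", {
  patch <- list(est = c(1950, 1980), bio = c(5, 2), deadwood = 0, soil = 0,
                phase = 0)
  none <- disturbance_step(patch, 0.5, 0, 2000)
  expect_null(none$killed)
  expect_identical(none$patch, patch)
  hit <- disturbance_step(patch, 0.0, 1 / 300, 2000)
  expect_equal(sum(hit$killed$biomass), 7)
  expect_equal(hit$killed$age, c(50, 20))
  expect_equal(sum(hit$patch$bio), 0)
  expect_identical(hit$patch$est, 2001)
  expect_error(disturbance_step(patch, 0.5, 1.2, 2000))
})

test_that("shared draws make lower-probability schedules event subsets", {
  # coupling property over a 100-year draw sequence, brute force
  set.seed(9)
  u <- runif(100)
  dT <- seq(0, 4, length.out = 100)
  pc <- disturbance_probability(1 / 300, dT, "constant")
  pe <- disturbance_probability(1 / 300, dT, "exponential")
  ev_c <- which(u < pc)
  ev_e <- which(u < pe)
  expect_true(all(ev_c %in% ev_e))
})

test_that("scheduled harvests honour phase, intensity switch, and the firewood age rule", {
  p <- stand_params("NE", n_patches = 1)
  scen <- default_scenario(harvest_intensity = 0)
  patch <- list(est = 1950, bio = 10, deadwood = 0, soil = 0, phase = 2030 %% 20)
  # intensity 0 after 2020: no event
  expect_null(scheduled_harvest(patch, 2030, scen, p)$event)
  # before the switch the multiplier is 1 regardless of the scenario level
  pre <- scheduled_harvest(list(est = 1950, bio = 10, deadwood = 0, soil = 0,
                                phase = 2010 %% 20), 2010, scen, p)
  expect_equal(pre$event$removed_stem + pre$event$firewood +
                 pre$event$residue, 0.24 * 10)
  # intensity 150% in 2030 removes fraction 0.36 of each cohort
  h <- scheduled_harvest(patch, 2030, default_scenario(harvest_intensity = 1.5), p)
  expect_equal(sum(10 - h$patch$bio[1]), 0.36 * 10)
  expect_equal(h$event$removed_stem, 0.36 * 10 * 0.65 * 0.9)
  # a 15-yr-old cohort is booked entirely as firewood
  yp <- list(est = 2015, bio = 1, deadwood = 0, soil = 0, phase = 2030 %% 20)
  hy <- scheduled_harvest(yp, 2030, default_scenario(harvest_intensity = 1), p)
  expect_equal(hy$event$firewood, 0.24)
  expect_equal(hy$event$removed_stem, 0)
  # off-phase year: nothing
  expect_null(scheduled_harvest(patch, 2031,
                                default_scenario(harvest_intensity = 1), p)$event)
})

test_that("dead-pool decay splits humification and respiration with Q10 scaling", {
  p <- stand_params("NE", n_patches = 1)
  patch <- list(est = 1950, bio = 1, deadwood = 1, soil = 0, phase = 0)
  d <- decay_dead_pools(patch, 0, p)
  expect_equal(d$patch$deadwood, 0.96)
  expect_equal(d$patch$soil, 0.012)
  expect_equal(d$deadwood_resp, 0.028)
  # dT = 10 doubles the rates under q10 = 2
  d10 <- decay_dead_pools(patch, 10, p)
  expect_equal(1 - d10$patch$deadwood, 0.08)
  # empty pools yield zero fluxes
  z <- decay_dead_pools(list(est = 1950, bio = 1, deadwood = 0, soil = 0,
                             phase = 0), 0, p)
  expect_equal(z$deadwood_resp + z$soil_resp, 0)
})

test_that("simulation is deterministic and closes the stand carbon balance", {
  clim <- generate_climate("RCP8.5", "site1", 5)
  scen <- default_scenario(salvage = TRUE)
  a <- simulate_stand(scen, clim, stand_params("NE", n_patches = 5), seed = 5)
  b <- simulate_stand(scen, clim, stand_params("NE", n_patches = 5), seed = 5)
  expect_identical(a, b)
  expect_lt(stand_closure_residual(a), 1e-9)
  expect_true(all(a$veg_c >= 0 & a$deadwood_c >= 0 & a$soil_c >= 0))
  # closure and nonnegativity across contrasting configurations
  for (scen2 in list(default_scenario(forest_type = "BD", forest_age = "young",
                                      harvest_intensity = 1.5),
                     default_scenario(harvest_intensity = 0, salvage = TRUE,
                                      disturbance_response = "constant"))) {
    s <- simulate_stand(scen2, clim,
                        stand_params(scen2$forest_type, n_patches = 4), seed = 2)
    expect_lt(stand_closure_residual(s), 1e-9)
    expect_true(all(s$veg_c >= 0 & s$deadwood_c >= 0 & s$soil_c >= 0))
  }
})

test_that("undisturbed unharvested stands approach the analytic equilibrium", {
  # fixed point of B' = npp_max (1 - B/K) - m B; the asymptote is below K
  # because background mortality persists (see methods vignette).
  p <- stand_params("NE", n_patches = 1, harvest_fraction = 0,
                    disturbance_interval = 1e9)
  st <- simulate_stand(default_scenario(), flat_climate(), p, seed = 1)
  b_star <- p$carrying_capacity * p$npp_max /
    (p$npp_max + p$background_mortality * p$carrying_capacity)
  expect_equal(st$veg_c[st$year == 2100], b_star, tolerance = 0.01)
})

test_that("disturbance event counts match the binomial oracle", {
  # constant p = 1/300 over 100 patches x 80 years: Binomial(8000, 1/300),
  # mean 26.67, sd 5.16; the seeded count must fall within 3 sd.
  clim <- generate_climate("RCP4.5", "site1", 42)
  st <- simulate_stand(default_scenario(disturbance_response = "constant"),
                       clim, stand_params("NE", n_patches = 100), seed = 42)
  n <- sum(st$disturbance_events[st$year %in% 1941:2020])
  mu <- 8000 / 300
  sd3 <- 3 * sqrt(8000 * (1 / 300) * (299 / 300))
  expect_gt(n, mu - sd3)
  expect_lt(n, mu + sd3)
})

test_that("salvage logging reroutes killed biomass from deadwood to removals", {
  clim <- generate_climate("RCP8.5", "site1", 5)
  p <- stand_params("NE", n_patches = 10)
  no <- simulate_stand(default_scenario(salvage = FALSE), clim, p, seed = 5)
  yes <- simulate_stand(default_scenario(salvage = TRUE), clim, p, seed = 5)
  # identical stochastic events (common random numbers)
  expect_identical(no$disturbance_events, yes$disturbance_events)
  pre <- no$year <= 2020
  expect_identical(no$removed_stem[pre], yes$removed_stem[pre])
  post <- no$year > 2020
  expect_true(sum(yes$removed_stem[post]) > sum(no$removed_stem[post]))
  expect_true(sum(yes$deadwood_c[post]) < sum(no$deadwood_c[post]))
})
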