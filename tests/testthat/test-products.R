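test_that("gamma decay calibration hits the median lifetimes", {
  specs <- default_decay_specs()
  for (cl in names(specs)) {
    sp <- specs[[cl]]
    expect_equal(product_survival(sp, sp$median_years), 0.5, tolerance = 1e-6)
    expect_equal(product_survival(sp, 0), 1)
  }
  # independent oracle: scale = median / qgamma(0.5, shape)
  expect_equal(gamma_decay_spec("long", 93, 2)$scale, 55.41166,
               tolerance = 1e-4)
  expect_error(gamma_decay_spec("long", -1))
  # survival curves are nonincreasing and start at 1
  t <- 0:400
  for (sp in specs) {
    s <- product_survival(sp, t)
    expect_true(all(diff(s) <= 0))
    expect_equal(s[1], 1)
  }
})

test_that("cascading extends the median at fixed scale", {
  sp <- gamma_decay_spec("long", 93, 2)
  expect_identical(apply_cascading(sp, 1), sp)
  c15 <- apply_cascading(sp, 1.5)
  expect_equal(c15$scale, sp$scale)
  expect_gt(c15$shape, sp$shape)
  # root-find then verify the median numerically
  expect_equal(product_survival(c15, 139.5), 0.5, tolerance = 1e-3)
  med <- uniroot(function(t) product_survival(c15, t) - 0.5,
                 c(93, 400), tol = 1e-8)$root
  expect_equal(med, 139.5, tolerance = 1e-3)
  # beyond the crossing point the cascaded curve survives longer
  expect_true(all(product_survival(c15, 100:400) >=
                    product_survival(sp, 100:400)))
  expect_error(apply_cascading(sp, 0.5))
})

test_that("usage fractions ramp to the printed 2050 shares and always close", {
  f <- usage_fractions("NE", 2050, 1.5)
  expect_equal(f[["long"]], 0.555)
  expect_equal(f[["medium"]], 0.255)
  # remainder 0.19 split across short and fuel in 36:10 proportion
  expect_equal(f[["short"]], 0.36 - 0.27 * 36 / 46, tolerance = 1e-10)
  expect_equal(f[["fuel"]], 1 - 0.555 - 0.255 - f[["short"]])
  # pre-2020 years keep the defaults even under the 150% scenario
  expect_equal(usage_fractions("BD", 2010, 1.5),
               c(long = 0.06, medium = 0.34, short = 0.25, fuel = 0.35))
  # closure and nonnegativity across the whole ramp, both forest types
  for (ft in c("NE", "BD")) for (y in 2020:2100) for (mu in c(1, 1.5)) {
    f <- usage_fractions(ft, y, mu)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f >= 0))
  }
  expect_error(usage_fractions("NE", 2050, 3.5),
               class = "forestmit_config_error")
  expect_error(usage_fractions("XX", 2050), class = "forestmit_config_error")
})

test_that("the vintage ledger decays cohorts with mass balance", {
  led <- product_ledger()
  led <- ledger_add(led, 2020, c(long = 1))
  # age 0: no decay in the creation year
  expect_equal(attr(ledger_step(led, 2020), "total"), 0)
  expect_equal(ledger_total(led, 2020), 1)
  # cumulative decay at the median age is one half
  dec <- vapply(2021:2113, function(y) attr(ledger_step(led, y), "total"), 0)
  expect_equal(sum(dec), 0.5, tolerance = 1e-6)
  # yearly identity: decays equal the drop in remaining carbon, and the
  # cumulative decay equals initial minus survival at any horizon
  for (y in c(2030, 2060, 2120)) {
    drop <- ledger_total(led, y - 1) - ledger_total(led, y)
    expect_equal(attr(ledger_step(led, y), "total"), drop, tolerance = 1e-12)
  }
  dec400 <- vapply(2021:2420, function(y) attr(ledger_step(led, y), "total"), 0)
  sp <- default_decay_specs()$long
  expect_equal(sum(dec400), 1 - product_survival(sp, 400), tolerance = 1e-12)
  # the Gamma tail with median 93 is still ~6e-3 at age 400; full
  # exhaustion to 1e-6 is only reached asymptotically (here by age 2000)
  dec2k <- vapply(2021:4020, function(y) attr(ledger_step(led, y), "total"), 0)
  expect_equal(sum(dec2k), 1, tolerance = 1e-6)
  expect_error(ledger_add(led, 2020, c(long = -1)))
})

test_that("vectorized product dynamics agree with the explicit ledger", {
  set.seed(7)
  years <- 2000:2100
  removed <- runif(length(years), 0, 0.2)
  firewood <- runif(length(years), 0, 0.05)
  for (cascade in c(1, 1.5)) {
    pd <- product_dynamics(removed, firewood, years, "NE",
                           material_usage = 1.5, cascade = cascade,
                           decarb_2050 = 0.5)
    # independent route: explicit cohort ledger
    specs <- default_decay_specs()
    led <- product_ledger()
    for (j in seq_along(years)) {
      fr <- usage_fractions("NE", years[j], 1.5)
      sp <- if (cascade > 1 && years[j] > 2020)
        lapply(specs, apply_cascading, factor = cascade) else specs
      led <- ledger_add(led, years[j],
                        removed[j] * fr[c("short", "medium", "long")], sp)
    }
    totals <- vapply(years, function(y) ledger_total(led, y), 0)
    decays <- vapply(years, function(y) attr(ledger_step(led, y), "total"), 0)
    pools <- pd$product_short_c + pd$product_medium_c + pd$product_long_c
    expect_equal(pools, totals, tolerance = 1e-9)
    expect_equal(pd$product_decay, decays, tolerance = 1e-9)
    # ledger mass balance: inflows minus decays equals the pool change
    expect_equal(diff(pools), (pd$product_inflow - pd$product_decay)[-1],
                 tolerance = 1e-12)
  }
})

test_that("cascading leaves pre-2021 vintages untouched", {
  years <- 2000:2100
  removed <- c(1, rep(0, length(years) - 1))  # single 2000 vintage
  a <- product_dynamics(removed, removed * 0, years, "NE", cascade = 1)
  b <- product_dynamics(removed, removed * 0, years, "NE", cascade = 1.5)
  expect_identical(a$product_long_c, b$product_long_c)
  expect_identical(a$product_decay, b$product_decay)
})
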