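single_group_baseline <- function(rate = 0.03, horizon = 66) {
  baseline_epidemiology(
    annual_perinatal_deaths = 10076, annual_maternal_deaths = 371,
    discount_rate = rate, perinatal_discount_horizon_years = horizon,
    maternal_age_distribution = data.frame(age_midpoint = 30, share = 1)
  )
}
repl <- rwanda_anc_inputs("replication")

test_that("deaths averted reproduce whole-death counts with half-up rounding", {
  expect_equal(deaths_averted(10076, 22.5), 2267)
  expect_equal(deaths_averted(10076, 55), 5542)
  expect_equal(deaths_averted(371, 7), 26)
  expect_equal(deaths_averted(371, 52.5), 195)
  expect_equal(deaths_averted(5000, 0), 0)
  expect_error(deaths_averted(-1, 10), ">= 0")
  expect_error(deaths_averted(100, 101), "\\[0, 100\\]")
})

test_that("deaths averted are monotone in the reduction and capped at baseline", {
  pcts <- seq(0, 100, by = 2.5)
  da <- deaths_averted(rep(371, length(pcts)), pcts)
  expect_true(all(diff(da) >= 0))
  expect_true(all(da <= 371))
  expect_equal(da[length(da)], 371)
})

test_that("annuity factor matches direct summation of discount factors", {
  for (r in c(0.01, 0.03, 0.08)) {
    for (n in c(1, 19, 36, 64, 66)) {
      expect_equal(annuity_factor(n, r), sum((1 + r)^-(1:n)), tolerance = 1e-12)
    }
  }
  expect_equal(annuity_factor(40, 0), 40)
  expect_equal(annuity_factor(64, 0.03), 28.306478, tolerance = 1e-6)
  expect_equal(annuity_factor(66, 0.03), 28.595040, tolerance = 1e-6)
  expect_equal(annuity_factor(36, 0.03), 21.832252, tolerance = 1e-6)
  expect_error(annuity_factor(10, -0.01), ">= 0")
})

test_that("annuity factor is below the horizon, increasing in it, decreasing in the rate", {
  ns <- 1:80
  a <- annuity_factor(ns, 0.03)
  expect_true(all(a < ns))
  expect_true(all(diff(a) > 0))
  rates <- seq(0.005, 0.1, by = 0.005)
  by_rate <- vapply(rates, annuity_factor, numeric(1), horizon_years = 50)
  expect_true(all(diff(by_rate) < 0))
})

test_that("perinatal life-years match the published cells within rounding drift", {
  # published 64,827 implies a 66-year factor of 64827/2267 = 28.5959,
  # which differs from the exact 28.5950 in the 4th decimal
  expect_equal(perinatal_lys(2267, repl$baseline), 64827, tolerance = 5e-5)
  expect_equal(perinatal_lys(2267, repl$baseline),
               2267 * annuity_factor(66, 0.03))
  expect_equal(perinatal_lys(1, single_group_baseline(rate = 0, horizon = 64)), 64)
  nom <- rwanda_anc_inputs("nominal")
  expect_equal(perinatal_lys(5542, nom$baseline), 156874.5, tolerance = 1e-5)
})

test_that("maternal life-years weight remaining female life expectancy by age at death", {
  b <- single_group_baseline()
  expect_equal(maternal_lys(10, b), 10 * 21.832252, tolerance = 1e-5)
  expect_equal(maternal_lys(10, single_group_baseline(rate = 0)), 360)
  expect_equal(maternal_lys(26, repl$baseline), 539, tolerance = 0.02)
  expect_error(baseline_epidemiology(
    10076, 371, maternal_age_distribution = data.frame(age_midpoint = 70, share = 1)),
    "below the female life expectancy")
})

test_that("health gains assemble both indicators and scale linearly", {
  opt <- health_gains(repl$baseline, list(label = "optimistic",
                                          perinatal_reduction_pct = 55,
                                          maternal_reduction_pct = 52.5))
  expect_equal(opt$total_lys, opt$perinatal_lys + opt$maternal_lys)
  expect_equal(opt$total_lys, 162509, tolerance = 1e-3)

  zero <- health_gains(repl$baseline, list(label = "none",
                                           perinatal_reduction_pct = 0,
                                           maternal_reduction_pct = 0))
  expect_equal(zero$total_lys, 0)
  expect_equal(zero$perinatal_deaths_averted, 0)

  half <- health_gains(repl$baseline, list(label = "half",
                                           perinatal_reduction_pct = 27.5,
                                           maternal_reduction_pct = 26.25))
  expect_lte(abs(2 * half$perinatal_deaths_averted - opt$perinatal_deaths_averted), 1)
  expect_lte(abs(2 * half$maternal_deaths_averted - opt$maternal_deaths_averted), 1)
})

test_that("age-share calibration hits its target factor and rejects infeasible ones", {
  mids <- seq(17.5, 47.5, by = 5)
  base <- c(0.08, 0.16, 0.22, 0.22, 0.17, 0.11, 0.04)
  target <- 4044 / 195
  d <- calibrate_age_shares(base, mids, target)
  expect_equal(sum(d$share), 1)
  horizons <- floor(66 - mids + 0.5)
  expect_equal(sum(d$share * annuity_factor(horizons, 0.03)), target,
               tolerance = 1e-12)
  expect_error(calibrate_age_shares(base, mids, 5), "outside the range")
  expect_error(calibrate_age_shares(base, mids, 30), "outside the range")
})

test_that("baseline epidemiology validates shares and rates", {
  bad_share <- data.frame(age_midpoint = c(25, 35), share = c(0.6, 0.5))
  expect_error(baseline_epidemiology(10076, 371,
                                     maternal_age_distribution = bad_share),
               "sum to 1")
  ok <- data.frame(age_midpoint = 30, share = 1)
  expect_error(baseline_epidemiology(10076, 371, discount_rate = 1,
                                     maternal_age_distribution = ok),
               "discount_rate")
  expect_error(baseline_epidemiology(-1, 371, maternal_age_distribution = ok),
               ">= 0")
})
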