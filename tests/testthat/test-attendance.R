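sc1 <- attendance_scenario("conservative", 5, 0.8, 1, 8)
sc2 <- attendance_scenario("mid", 6, 0.8, 2, 10)
eight <- who_eight_visit_schedule()

test_that("scenario construction enforces its invariants", {
  expect_error(attendance_scenario("x", 5, 0.8, 6, 8), "mean_visits")
  expect_error(attendance_scenario("x", 5, -1, 1, 8), "sd_visits")
  expect_error(attendance_scenario("x", 5, 0.8, 0, 8), "min_visits")
  expect_error(attendance_scenario("x", 4.5, 0, 4, 5, degenerate = TRUE),
               "integer mean_visits")
})

test_that("degenerate scenarios give every woman exactly the mean visit count", {
  fu <- attendance_scenario("full", 4, 0, 4, 4, degenerate = TRUE)
  expect_identical(draw_visit_counts(fu, 10, seed = 1), rep(4L, 10))
})

test_that("draws stay in bounds and are reproducible under a fixed seed", {
  for (seed in c(3, 17, 99)) {
    x <- draw_visit_counts(sc2, 5000, seed = seed)
    expect_true(all(x >= 2 & x <= 10))
    expect_identical(x, draw_visit_counts(sc2, 5000, seed = seed))
  }
  expect_error(draw_visit_counts(sc1, 0, seed = 1), "cohort_size")
})

test_that("a national-cohort draw recovers the scenario mean and observed extremes", {
  x <- draw_visit_counts(sc1, 373679, seed = 13)
  expect_lt(abs(mean(x) - 5), 3 * 0.8 / sqrt(373679))
  expect_identical(range(x), c(1L, 8L))  # tails of ~374k rounded normal draws
})

test_that("closed-form per-woman cost matches hand-derived and point-mass values", {
  cf1 <- expected_cost_closed_form(eight, sc1)
  expect_equal(cf1$mean, 53.0648, tolerance = 1e-4)  # hand sum over k = 1..8
  expect_equal(cf1$sd, 6.617, tolerance = 1e-3)

  fu5 <- attendance_scenario("point", 5, 0, 5, 5, degenerate = TRUE)
  expect_equal(expected_cost_closed_form(eight, fu5)$mean,
               cumulative_cost(eight, 5))

  expect_equal(round(expected_cost_closed_form(eight, sc2)$mean), 61)
})

test_that("closed form equals direct enumeration of the discretised clipped normal", {
  # independent oracle: explicit probability mass over counts
  for (sc in list(sc1, sc2, attendance_scenario("narrow", 4, 0.3, 2, 6))) {
    ks <- sc$min_visits:sc$max_visits
    lo <- c(-Inf, ks[-length(ks)] + 0.5)
    hi <- c(ks[-length(ks)] + 0.5, Inf)
    p <- pnorm(hi, sc$mean_visits, sc$sd_visits) -
      pnorm(lo, sc$mean_visits, sc$sd_visits)
    costs <- cumulative_cost(eight, ks)
    cf <- expected_cost_closed_form(eight, sc)
    expect_equal(cf$mean, sum(p * costs), tolerance = 1e-12)
    expect_equal(cf$sd, sqrt(sum(p * costs^2) - sum(p * costs)^2),
                 tolerance = 1e-9)
  }
})

test_that("simulated per-woman mean converges to the closed-form oracle", {
  set.seed(1234)
  for (case in 1:4) {
    costs <- round(runif(sample(3:9, 1), 0, 30), 2)
    sched <- visit_cost_schedule("random", costs,
                                 overflow_visit_cost = sample(0:8, 1))
    mu <- runif(1, 2, 7)
    sc <- attendance_scenario("random", mu, runif(1, 0.4, 1.5),
                              max(1, floor(mu - 3)), ceiling(mu + 3))
    sim <- simulate_cost_distribution(sched, sc, cohort_size = 20000,
                                      n_replications = 20, seed = 100 + case)
    cf <- expected_cost_closed_form(sched, sc)
    mcse <- cf$sd / sqrt(20000 * 20)
    expect_lt(abs(sim$mean_cost_per_woman - cf$mean), 3 * mcse + 1e-9)
    expect_equal(sim$sd_cost_per_woman, cf$sd, tolerance = 0.05)
  }
})

test_that("expected cost is monotone in the scenario mean", {
  means <- seq(3, 7, by = 1)
  expected <- vapply(means, function(m) {
    expected_cost_closed_form(eight, attendance_scenario("m", m, 0.8, 1, 11))$mean
  }, numeric(1))
  expect_true(all(diff(expected) > 0))
})

test_that("simulation results are deterministic and internally consistent", {
  a <- simulate_cost_distribution(eight, sc1, 5000, n_replications = 10, seed = 5)
  b <- simulate_cost_distribution(eight, sc1, 5000, n_replications = 10, seed = 5)
  expect_identical(a$total_cost_per_replication, b$total_cost_per_replication)
  expect_true(a$min_total <= a$mean_total && a$mean_total <= a$max_total)
  expect_equal(a$mean_cost_per_woman, a$mean_total / 5000)
  expect_gte(a$relative_spread, 0)
})

test_that("relative spread check reproduces arithmetic on reported totals", {
  # published scenario-1 replication range: min/max/mean of the 100 totals
  fake <- structure(list(scenario_label = "tab", n_replications = 100L,
                         mean_total = 19829260, min_total = 19818549,
                         max_total = 19837028,
                         relative_spread = (19837028 - 19818549) / 19829260),
                    class = "cost_simulation_result")
  chk <- relative_spread_check(fake, threshold = 0.002)
  expect_equal(chk$spread, 9.318e-4, tolerance = 1e-3)
  expect_true(chk$pass)

  fu <- attendance_scenario("full", 4, 0, 4, 4, degenerate = TRUE)
  const <- simulate_cost_distribution(rwanda_four_visit_schedule(), fu, 1000,
                                      n_replications = 5, seed = 2)
  expect_equal(relative_spread_check(const)$spread, 0)
  one <- simulate_cost_distribution(eight, sc1, 100, n_replications = 1, seed = 2)
  expect_error(relative_spread_check(one), "2 replications")
})
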