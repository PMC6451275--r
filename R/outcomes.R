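#' Baseline epidemiology for the life-years-saved calculation
#'
#' Bundles the national inputs used to convert mortality reductions into
#' deaths averted and discounted life-years saved (LYS): annual death counts,
#' life expectancies, the discount rate, the perinatal discounting horizon,
#' and the age distribution of maternal deaths. Rwandan defaults: 10,076
#' perinatal and 371 maternal deaths (2015 health statistics), life
#' expectancy at birth 64 years (both sexes) and 66 years (women, 2012
#' census), 3% annual discounting.
#'
#' @param annual_perinatal_deaths Baseline perinatal deaths per year.
#' @param annual_maternal_deaths Baseline maternal deaths per year.
#' @param life_expectancy_both_sexes Life expectancy at birth, both sexes
#'   (years).
#' @param life_expectancy_female Life expectancy at birth, women (years).
#' @param discount_rate Annual discount rate in `[0, 1)`.
#' @param perinatal_discount_horizon_years Horizon (years) over which one
#'   averted perinatal death accrues life-years. See [rwanda_anc_inputs()]
#'   for the two shipped conventions (64 vs 66).
#' @param maternal_age_distribution Data frame with columns `age_midpoint`
#'   (years, each below `life_expectancy_female`) and `share` (fractions
#'   summing to 1): the age distribution of maternal deaths.
#' @param perinatal_mortality_rate Descriptive, deaths per 1000 pregnancies.
#' @param maternal_mortality_ratio Descriptive, deaths per 100,000 live
#'   births.
#'
#' @return An object of class `baseline_epidemiology`.
#' @export
baseline_epidemiology <- function(annual_perinatal_deaths,
                                  annual_maternal_deaths,
                                  life_expectancy_both_sexes = 64,
                                  life_expectancy_female = 66,
                                  discount_rate = 0.03,
                                  perinatal_discount_horizon_years =
                                    life_expectancy_both_sexes,
                                  maternal_age_distribution,
                                  perinatal_mortality_rate = NA_real_,
                                  maternal_mortality_ratio = NA_real_) {
  if (annual_perinatal_deaths < 0 || annual_maternal_deaths < 0) {
    stop_("death counts must be >= 0")
  }
  if (discount_rate < 0 || discount_rate >= 1) {
    stop_("discount_rate must be in [0, 1)")
  }
  if (perinatal_discount_horizon_years < 0) {
    stop_("perinatal_discount_horizon_years must be >= 0")
  }
  d <- maternal_age_distribution
  if (!is.data.frame(d) || !all(c("age_midpoint", "share") %in% names(d))) {
    stop_("maternal_age_distribution must have columns age_midpoint and share")
  }
  if (abs(sum(d$share) - 1) > 1e-9) {
    stop_("maternal age distribution shares must sum to 1")
  }
  if (any(d$share < 0)) stop_("maternal age shares must be >= 0")
  if (any(d$age_midpoint >= life_expectancy_female)) {
    stop_("every maternal age midpoint must be below the female life expectancy")
  }
  structure(
    list(
      annual_perinatal_deaths = annual_perinatal_deaths,
      annual_maternal_deaths = annual_maternal_deaths,
      life_expectancy_both_sexes = life_expectancy_both_sexes,
      life_expectancy_female = life_expectancy_female,
      discount_rate = discount_rate,
      perinatal_discount_horizon_years = perinatal_discount_horizon_years,
      maternal_age_distribution = d,
      perinatal_mortality_rate = perinatal_mortality_rate,
      maternal_mortality_ratio = maternal_mortality_ratio
    ),
    class = "baseline_epidemiology"
  )
}

#' Deaths averted by a percentage mortality reduction
#'
#' `baseline_deaths * reduction_pct / 100`, rounded half up to a whole
#' number of deaths.
#'
#' @param baseline_deaths Annual baseline deaths (>= 0).
#' @param reduction_pct Percentage reduction in `[0, 100]`.
#' @return Whole number of deaths averted (never exceeds
#'   `baseline_deaths`).
#' @export
#' @examples
#' deaths_averted(10076, 22.5) # 2267
deaths_averted <- function(baseline_deaths, reduction_pct) {
  if (any(baseline_deaths < 0)) stop_("baseline_deaths must be >= 0")
  if (any(reduction_pct < 0 | reduction_pct > 100)) {
    stop_("reduction_pct must be in [0, 100]")
  }
  pmin(round_half_up(baseline_deaths * reduction_pct / 100), baseline_deaths)
}

#' Present value of one life-year per year over a horizon
#'
#' Standard end-of-year annuity factor `(1 - (1 + r)^-n) / r`, reducing to
#' `n` when `r = 0`. Discounted life-years per averted death.
#'
#' @param horizon_years Number of years (>= 0); vectorised.
#' @param discount_rate Annual rate (>= 0).
#' @return Discounted years, same length as `horizon_years`.
#' @export
#' @examples
#' annuity_factor(66, 0.03)
annuity_factor <- function(horizon_years, discount_rate) {
  if (any(horizon_years < 0)) stop_("horizon_years must be >= 0")
  if (length(discount_rate) != 1L || discount_rate < 0) {
    stop_("discount_rate must be a single number >= 0")
  }
  if (discount_rate == 0) {
    return(as.numeric(horizon_years))
  }
  (1 - (1 + discount_rate)^(-horizon_years)) / discount_rate
}

#' Discounted life-years saved from averted perinatal deaths
#'
#' Each averted perinatal death saves a full life, discounted over the
#' configured perinatal horizon.
#'
#' @param deaths_averted Number of perinatal deaths averted.
#' @param baseline A [baseline_epidemiology()].
#' @return Discounted life-years (full precision; round only for reporting).
#' @export
perinatal_lys <- function(deaths_averted, baseline) {
  stopifnot(inherits(baseline, "baseline_epidemiology"))
  deaths_averted * annuity_factor(baseline$perinatal_discount_horizon_years,
                                  baseline$discount_rate)
}

#' Discounted life-years saved from averted maternal deaths
#'
#' A woman dying at age `a` loses her remaining life expectancy
#' `round(life_expectancy_female - a)` years; averted deaths are spread over
#' the maternal age-at-death distribution.
#'
#' @inheritParams perinatal_lys
#' @return Discounted life-years.
#' @export
maternal_lys <- function(deaths_averted, baseline) {
  stopifnot(inherits(baseline, "baseline_epidemiology"))
  d <- baseline$maternal_age_distribution
  horizons <- round_half_up(baseline$life_expectancy_female - d$age_midpoint)
  deaths_averted * sum(d$share * annuity_factor(horizons, baseline$discount_rate))
}

#' Health gains of one outcome scenario
#'
#' Converts a scenario's paired mortality reductions into deaths averted and
#' discounted LYS for both indicators.
#'
#' @param baseline A [baseline_epidemiology()].
#' @param scenario One row of an [outcome_scenarios()] data frame (or any
#'   list with `label`, `perinatal_reduction_pct`, `maternal_reduction_pct`).
#' @return An object of class `health_gains`: scenario label, deaths averted
#'   and LYS per indicator, and `total_lys`.
#' @export
health_gains <- function(baseline, scenario) {
  stopifnot(inherits(baseline, "baseline_epidemiology"))
  dp <- deaths_averted(baseline$annual_perinatal_deaths,
                       scenario$perinatal_reduction_pct)
  dm <- deaths_averted(baseline$annual_maternal_deaths,
                       scenario$maternal_reduction_pct)
  pl <- perinatal_lys(dp, baseline)
  ml <- maternal_lys(dm, baseline)
  structure(
    list(scenario_label = as.character(scenario$label),
         perinatal_reduction_pct = scenario$perinatal_reduction_pct,
         maternal_reduction_pct = scenario$maternal_reduction_pct,
         perinatal_deaths_averted = dp,
         maternal_deaths_averted = dm,
         perinatal_lys = pl,
         maternal_lys = ml,
         total_lys = pl + ml),
    class = "health_gains"
  )
}

#' @export
print.health_gains <- function(x, ...) {
  cat(sprintf("<health_gains> %s\n", x$scenario_label))
  cat(sprintf("  perinatal: -%s%% -> %d deaths averted, %s LYS\n",
              x$perinatal_reduction_pct, x$perinatal_deaths_averted,
              format(round(x$perinatal_lys), big.mark = ",")))
  cat(sprintf("  maternal:  -%s%% -> %d deaths averted, %s LYS\n",
              x$maternal_reduction_pct, x$maternal_deaths_averted,
              format(round(x$maternal_lys), big.mark = ",")))
  cat(sprintf("  total: %s LYS\n", format(round(x$total_lys), big.mark = ",")))
  invisible(x)
}

#' Calibrate maternal age shares to a target discounted-years factor
#'
#' Given a plausible base age-at-death distribution, finds the mixture
#' `(1 - t) * base + t * point-mass` (on the age group with the most extreme
#' annuity factor in the needed direction) whose implied discounted years
#' per maternal death equals `target_factor`. The factor is linear in `t`,
#' so the solution is closed-form; an unattainable target is an error.
#'
#' @param base_shares Non-negative shares summing to 1.
#' @param age_midpoints Age-group midpoints (years), same length.
#' @param target_factor Target discounted life-years per maternal death.
#' @param life_expectancy_female Female life expectancy at birth (years).
#' @param discount_rate Annual discount rate.
#' @return Data frame with columns `age_midpoint` and `share`, suitable for
#'   [baseline_epidemiology()].
#' @export
calibrate_age_shares <- function(base_shares, age_midpoints, target_factor,
                                 life_expectancy_female = 66,
                                 discount_rate = 0.03) {
  stopifnot(length(base_shares) == length(age_midpoints))
  if (abs(sum(base_shares) - 1) > 1e-9 || any(base_shares < 0)) {
    stop_("base_shares must be non-negative and sum to 1")
  }
  horizons <- round_half_up(life_expectancy_female - age_midpoints)
  if (any(horizons < 0)) stop_("age midpoints must be below life expectancy")
  f <- annuity_factor(horizons, discount_rate)
  f0 <- sum(base_shares * f)
  if (abs(f0 - target_factor) < 1e-12) {
    t <- 0
    k <- 1L
  } else {
    k <- if (target_factor < f0) which.min(f) else which.max(f)
    t <- (f0 - target_factor) / (f0 - f[k])
    if (!is.finite(t) || t < 0 || t > 1) {
      stop_("target factor %.4f is outside the range achievable from the base distribution", target_factor)
    }
  }
  shares <- (1 - t) * base_shares
  shares[k] <- shares[k] + t
  data.frame(age_midpoint = age_midpoints, share = shares)
}
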