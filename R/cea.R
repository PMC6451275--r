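#' Configuration for the cost-effectiveness comparison
#'
#' Fixed comparator and threshold inputs: the current-practice national ANC
#' cost (taken as a known input from primary micro-costing, not
#' re-simulated), the cohort size, and the GDP-per-capita willingness-to-pay
#' thresholds. An intervention averting one life-year for at most 1x GDP per
#' capita is "very cost-effective"; above 3x it is "not cost-effective"
#' (boundaries inclusive).
#'
#' @param comparator_total_cost Current-practice national annual ANC cost
#'   (USD). Rwandan default 13,939,970.
#' @param comparator_cost_per_woman Current-practice average cost per woman
#'   (USD). Default 37.
#' @param cohort_size Women attending ANC at least once per year. Default
#'   373,679.
#' @param gdp_per_capita GDP per capita (USD). Rwandan 2015 default 697.
#' @param very_ce_multiplier,not_ce_multiplier Threshold multiples of GDP
#'   per capita (defaults 1 and 3).
#' @return An object of class `cea_config`.
#' @export
cea_config <- function(comparator_total_cost = 13939970,
                       comparator_cost_per_woman = 37,
                       cohort_size = 373679,
                       gdp_per_capita = 697,
                       very_ce_multiplier = 1,
                       not_ce_multiplier = 3) {
  vals <- c(comparator_total_cost, comparator_cost_per_woman,
            cohort_size, gdp_per_capita)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_("all monetary values and the cohort size must be positive")
  }
  if (not_ce_multiplier < very_ce_multiplier) {
    stop_("not_ce_multiplier must be >= very_ce_multiplier")
  }
  structure(
    list(comparator_total_cost = comparator_total_cost,
         comparator_cost_per_woman = comparator_cost_per_woman,
         cohort_size = as.integer(cohort_size),
         gdp_per_capita = gdp_per_capita,
         very_ce_multiplier = very_ce_multiplier,
         not_ce_multiplier = not_ce_multiplier),
    class = "cea_config"
  )
}

#' Incremental cost of a costing scenario over the comparator
#'
#' @param new_total Total cost (USD) under the new schedule scenario.
#' @param comparator_total Total cost (USD) of current practice.
#' @return `new_total - comparator_total`. May be negative (cost saving);
#'   downstream reports flag that case.
#' @export
incremental_cost <- function(new_total, comparator_total) {
  if (any(new_total < 0) || any(comparator_total < 0)) {
    stop_("costs must be >= 0")
  }
  new_total - comparator_total
}

#' Incremental cost-effectiveness ratio
#'
#' Cost per life-year saved: `incremental_cost / lys`. Non-positive LYS make
#' the ratio undefined (dominance analysis is out of scope).
#'
#' @param incremental_cost Incremental cost (USD).
#' @param lys Life-years saved (> 0).
#' @return USD per life-year saved.
#' @export
#' @examples
#' icer(5889290, 162509) # ~36.2
icer <- function(incremental_cost, lys) {
  if (any(lys <= 0)) stop_("undefined ICER: life-years saved must be > 0")
  incremental_cost / lys
}

#' Classify an ICER against GDP-based thresholds
#'
#' @param icer_value ICER(s), USD per life-year saved (>= 0); vectorised.
#' @param config A [cea_config()].
#' @return Character vector: `"very-cost-effective"` (<= 1x GDP per capita),
#'   `"cost-effective"` (<= 3x), or `"not-cost-effective"` (> 3x).
#' @export
#' @examples
#' classify_icer(c(36, 697, 2092), cea_config())
classify_icer <- function(icer_value, config) {
  stopifnot(inherits(config, "cea_config"))
  if (any(icer_value < 0)) stop_("icer_value must be >= 0")
  very <- config$very_ce_multiplier * config$gdp_per_capita
  upper <- config$not_ce_multiplier * config$gdp_per_capita
  ifelse(icer_value <= very, "very-cost-effective",
         ifelse(icer_value <= upper, "cost-effective", "not-cost-effective"))
}

#' Cross costing and outcome scenarios into the ICER matrix
#'
#' One cell per (costing scenario, outcome scenario) pair; every pair is
#' combined, including pairings one might consider unlikely (e.g. high
#' attendance with the pessimistic outcome), since no joint model of
#' attendance and effectiveness is assumed.
#'
#' @param cost_results List of [simulate_cost_distribution()] results (one
#'   per costing scenario).
#' @param gains List of [health_gains()] objects (one per outcome scenario).
#' @param config A [cea_config()].
#' @return A data frame of class `cea_table`, one row per cell:
#'   `costing_scenario`, `outcome_scenario`, `incremental_cost`, `lys`,
#'   `icer` (full precision), `icer_rounded` (half-up to whole dollars),
#'   `classification`, and `cost_saving` (negative incremental cost flag).
#' @export
build_cea_table <- function(cost_results, gains, config) {
  stopifnot(inherits(config, "cea_config"))
  if (!length(cost_results) || !length(gains)) {
    stop_("need at least one costing and one outcome scenario")
  }
  rows <- list()
  for (cr in cost_results) {
    stopifnot(inherits(cr, "cost_simulation_result"))
    inc <- incremental_cost(cr$mean_total, config$comparator_total_cost)
    for (g in gains) {
      stopifnot(inherits(g, "health_gains"))
      val <- icer(inc, g$total_lys)
      rows[[length(rows) + 1L]] <- data.frame(
        costing_scenario = cr$scenario_label,
        outcome_scenario = g$scenario_label,
        incremental_cost = inc,
        lys = g$total_lys,
        icer = val,
        icer_rounded = round_half_up(val),
        classification = if (val >= 0) classify_icer(val, config) else NA_character_,
        cost_saving = inc < 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cea_table", "data.frame")
  out
}
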