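#' Construct a per-visit cost schedule
#'
#' A visit cost schedule holds the unit cost of each scheduled antenatal care
#' (ANC) visit, in order, plus the cost applied to every visit a woman attends
#' beyond the scheduled count ("overflow" visits). All amounts are 2015 USD.
#'
#' @param label Short name for the schedule.
#' @param unit_costs Numeric vector of per-visit unit costs (USD), one per
#'   scheduled visit, in visit order. Must be non-empty and non-negative.
#' @param overflow_visit_cost Cost (USD) of each visit beyond the scheduled
#'   count. Defaults to 6, the price of an ordinary routine visit with no
#'   scheduled tests.
#'
#' @return An object of class `visit_cost_schedule`.
#' @seealso [cumulative_cost()], [full_compliance_cost()],
#'   [rwanda_four_visit_schedule()], [who_eight_visit_schedule()]
#' @export
#' @examples
#' visit_cost_schedule("toy", c(10, 5, 5), overflow_visit_cost = 5)
visit_cost_schedule <- function(label, unit_costs, overflow_visit_cost = 6) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_("schedule label must be a non-empty string")
  }
  if (!is.numeric(unit_costs) || length(unit_costs) == 0L) {
    stop_("unit_costs must be a non-empty numeric vector")
  }
  if (anyNA(unit_costs) || any(unit_costs < 0)) {
    stop_("all unit costs must be non-negative")
  }
  if (!is.numeric(overflow_visit_cost) || length(overflow_visit_cost) != 1L ||
      is.na(overflow_visit_cost) || overflow_visit_cost < 0) {
    stop_("overflow_visit_cost must be a single non-negative number")
  }
  structure(
    list(
      label = label,
      unit_costs = as.numeric(unit_costs),
      overflow_visit_cost = as.numeric(overflow_visit_cost)
    ),
    class = "visit_cost_schedule"
  )
}

#' @export
print.visit_cost_schedule <- function(x, ...) {
  cat(sprintf("<visit_cost_schedule> %s\n", x$label))
  cat(sprintf("  %d scheduled visits, unit costs (USD): %s\n",
              length(x$unit_costs), paste(x$unit_costs, collapse = ", ")))
  cat(sprintf("  overflow visit cost: %s; full-compliance cost: %s\n",
              x$overflow_visit_cost, full_compliance_cost(x)))
  invisible(x)
}

#' Cost of attending the first n visits of a schedule
#'
#' Attending `k` visits is costed as receiving the content of scheduled
#' visits `1..k` in order; visits beyond the schedule length each add
#' `overflow_visit_cost`. Vectorised over `n_visits`.
#'
#' @param schedule A [visit_cost_schedule()].
#' @param n_visits Positive integer(s): number of visits attended. The cohort
#'   is defined as women attending at least once, so values below 1 are an
#'   error.
#'
#' @return Numeric vector of cumulative costs (USD), same length as
#'   `n_visits`.
#' @export
#' @examples
#' cumulative_cost(who_eight_visit_schedule(), 1)   # first contact incl. ultrasound
#' cumulative_cost(rwanda_four_visit_schedule(), 4) # full four-visit schedule
cumulative_cost <- function(schedule, n_visits) {
  stopifnot(inherits(schedule, "visit_cost_schedule"))
  if (length(n_visits) == 0L) return(numeric(0))
  if (!is.numeric(n_visits) || anyNA(n_visits) || any(n_visits < 1) ||
      any(n_visits != floor(n_visits))) {
    stop_("invalid attendance: n_visits must be whole numbers >= 1 (every woman in the cohort attends at least one visit)")
  }
  k <- length(schedule$unit_costs)
  cum <- cumsum(schedule$unit_costs)
  within <- pmin.int(n_visits, k)
  extra <- pmax.int(n_visits - k, 0)
  cum[within] + extra * schedule$overflow_visit_cost
}

#' Cost of full compliance with a schedule
#'
#' The per-woman cost when every scheduled visit is attended, i.e.
#' [cumulative_cost()] evaluated at the schedule's own length.
#'
#' @inheritParams cumulative_cost
#' @return A single cost (USD).
#' @export
#' @examples
#' full_compliance_cost(rwanda_four_visit_schedule()) # 44
full_compliance_cost <- function(schedule) {
  stopifnot(inherits(schedule, "visit_cost_schedule"))
  cumulative_cost(schedule, length(schedule$unit_costs))
}

#' Built-in schedules: current Rwandan four-visit ANC and 2016 WHO eight-contact ANC
#'
#' Unit costs (2015 USD) from micro-costing of current practice in Rwandan
#' public facilities, and the derived assumptions for the eight-contact
#' schedule: first contact adds a $3 obstetric ultrasound to the current $21
#' first visit; contacts 3 and 6 are routine visits ($6) plus repeat
#' bacteriuria ($3) and anaemia ($0.75) tests, rounded to $10; the final
#' visit costs $11 in both schedules.
#'
#' @param overflow_visit_cost Cost of visits beyond the scheduled count; see
#'   [visit_cost_schedule()].
#' @return A [visit_cost_schedule()].
#' @export
rwanda_four_visit_schedule <- function(overflow_visit_cost = 6) {
  visit_cost_schedule("current-practice-four-visit", c(21, 6, 6, 11),
                      overflow_visit_cost = overflow_visit_cost)
}

#' @rdname rwanda_four_visit_schedule
#' @export
who_eight_visit_schedule <- function(overflow_visit_cost = 6) {
  visit_cost_schedule("who-2016-eight-contact", c(24, 6, 10, 6, 6, 10, 6, 11),
                      overflow_visit_cost = overflow_visit_cost)
}
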