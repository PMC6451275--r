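#' Define an ANC attendance scenario
#'
#' An attendance scenario is a policy world describing how many ANC visits
#' women attend: a normal distribution of visit counts with the given mean
#' and standard deviation, discretised (rounded half away from zero) and
#' clipped to `[min_visits, max_visits]`. A `degenerate` scenario is the
#' full-utilisation counterfactual in which every woman attends exactly
#' `mean_visits` visits.
#'
#' @param label Scenario name.
#' @param mean_visits Mean number of visits per woman.
#' @param sd_visits Standard deviation of visits (>= 0; must be > 0 unless
#'   `degenerate`).
#' @param min_visits Minimum visits (integer >= 1; the cohort attends at
#'   least once).
#' @param max_visits Maximum visits (integer >= `min_visits`).
#' @param degenerate If `TRUE`, all women attend exactly `mean_visits`
#'   (which must then be an integer).
#'
#' @return An object of class `attendance_scenario`.
#' @export
#' @examples
#' attendance_scenario("conservative", 5, 0.8, 1, 8)
#' attendance_scenario("full-utilisation", 4, 0, 4, 4, degenerate = TRUE)
attendance_scenario <- function(label, mean_visits, sd_visits,
                                min_visits, max_visits, degenerate = FALSE) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_("scenario label must be a non-empty string")
  }
  stopifnot(is.numeric(mean_visits), is.numeric(sd_visits),
            length(mean_visits) == 1L, length(sd_visits) == 1L)
  if (sd_visits < 0) stop_("sd_visits must be >= 0")
  if (!is_count(min_visits)) stop_("min_visits must be an integer >= 1")
  if (!is.numeric(max_visits) || max_visits != floor(max_visits) ||
      max_visits < min_visits) {
    stop_("max_visits must be an integer >= min_visits")
  }
  if (mean_visits < min_visits || mean_visits > max_visits) {
    stop_("mean_visits must lie in [min_visits, max_visits]")
  }
  if (degenerate && mean_visits != floor(mean_visits)) {
    stop_("a degenerate scenario requires an integer mean_visits")
  }
  structure(
    list(label = label, mean_visits = mean_visits, sd_visits = sd_visits,
         min_visits = as.integer(min_visits), max_visits = as.integer(max_visits),
         degenerate = isTRUE(degenerate)),
    class = "attendance_scenario"
  )
}

#' @export
print.attendance_scenario <- function(x, ...) {
  cat(sprintf("<attendance_scenario> %s: mean %s, sd %s, range [%d, %d]%s\n",
              x$label, x$mean_visits, x$sd_visits, x$min_visits, x$max_visits,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Draw per-woman visit counts for a scenario
#'
#' Draws `cohort_size` visit counts from the scenario's discretised clipped
#' normal distribution: continuous normal draws are rounded half away from
#' zero to integers and clipped to `[min_visits, max_visits]`. Degenerate
#' scenarios return `mean_visits` for every woman.
#'
#' @param scenario An [attendance_scenario()].
#' @param cohort_size Number of women (>= 1).
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#'
#' @return Integer vector of length `cohort_size`.
#' @export
draw_visit_counts <- function(scenario, cohort_size, seed) {
  stopifnot(inherits(scenario, "attendance_scenario"))
  if (!is_count(cohort_size)) stop_("cohort_size must be a positive integer")
  if (scenario$degenerate) {
    return(rep.int(as.integer(scenario$mean_visits), cohort_size))
  }
  if (scenario$sd_visits <= 0) {
    stop_("sd_visits must be > 0 for a non-degenerate scenario")
  }
  set.seed(as.integer(seed))
  x <- stats::rnorm(cohort_size, scenario$mean_visits, scenario$sd_visits)
  counts <- sign(x) * floor(abs(x) + 0.5)
  as.integer(pmin.int(pmax.int(counts, scenario$min_visits), scenario$max_visits))
}

#' Closed-form per-woman cost under a scenario
#'
#' Exact expectation and standard deviation of [cumulative_cost()] under the
#' discretised clipped normal attendance model: the probability of attending
#' `k` visits is `pnorm(k + 0.5, m, s) - pnorm(k - 0.5, m, s)`, with all tail
#' mass folded into `min_visits` and `max_visits`. Serves as an independent
#' oracle for [simulate_cost_distribution()].
#'
#' @param schedule A [visit_cost_schedule()].
#' @param scenario An [attendance_scenario()].
#'
#' @return A list with elements `mean` and `sd` (USD per woman).
#' @export
expected_cost_closed_form <- function(schedule, scenario) {
  stopifnot(inherits(schedule, "visit_cost_schedule"),
            inherits(scenario, "attendance_scenario"))
  if (scenario$degenerate || scenario$sd_visits == 0) {
    return(list(mean = cumulative_cost(schedule, scenario$mean_visits), sd = 0))
  }
  ks <- scenario$min_visits:scenario$max_visits
  p <- stats::pnorm(ks + 0.5, scenario$mean_visits, scenario$sd_visits) -
    stats::pnorm(ks - 0.5, scenario$mean_visits, scenario$sd_visits)
  p[1L] <- p[1L] + stats::pnorm(ks[1L] - 0.5, scenario$mean_visits, scenario$sd_visits)
  n <- length(ks)
  p[n] <- p[n] + stats::pnorm(ks[n] + 0.5, scenario$mean_visits, scenario$sd_visits,
                              lower.tail = FALSE)
  costs <- cumulative_cost(schedule, ks)
  m <- sum(p * costs)
  v <- sum(p * costs^2) - m^2
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Monte Carlo simulation of the national ANC cost distribution
#'
#' For each replication, draws visit counts for the whole cohort, costs each
#' woman with [cumulative_cost()], and sums to a national total. One RNG
#' stream per replication is derived from the master seed, so results do not
#' depend on execution order.
#'
#' @inheritParams expected_cost_closed_form
#' @param cohort_size Number of women per replication.
#' @param n_replications Number of independent replications (default 100).
#' @param seed Master integer seed.
#'
#' @return An object of class `cost_simulation_result`: a list with the
#'   scenario label, per-replication totals, mean/min/max total, mean and SD
#'   of per-woman cost, the relative spread `(max - min) / mean`, and the
#'   inputs used.
#' @seealso [relative_spread_check()], [expected_cost_closed_form()]
#' @export
simulate_cost_distribution <- function(schedule, scenario, cohort_size,
                                       n_replications = 100, seed) {
  stopifnot(inherits(schedule, "visit_cost_schedule"),
            inherits(scenario, "attendance_scenario"))
  if (!is_count(cohort_size)) stop_("cohort_size must be a positive integer")
  if (!is_count(n_replications)) stop_("n_replications must be a positive integer")

  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_replications)

  lookup <- cumulative_cost(schedule, scenario$min_visits:scenario$max_visits)
  totals <- numeric(n_replications)
  sumsq <- numeric(n_replications)
  for (i in seq_len(n_replications)) {
    counts <- draw_visit_counts(scenario, cohort_size, seed = sub_seeds[i])
    cw <- lookup[counts - scenario$min_visits + 1L]
    totals[i] <- sum(cw)
    sumsq[i] <- sum(cw * cw)
  }
  mean_total <- mean(totals)
  per_rep_var <- pmax(sumsq / cohort_size - (totals / cohort_size)^2, 0)
  structure(
    list(
      scenario_label = scenario$label,
      schedule_label = schedule$label,
      n_replications = n_replications,
      cohort_size = cohort_size,
      seed = as.integer(seed),
      total_cost_per_replication = totals,
      mean_total = mean_total,
      min_total = min(totals),
      max_total = max(totals),
      mean_cost_per_woman = mean_total / cohort_size,
      sd_cost_per_woman = mean(sqrt(per_rep_var)),
      relative_spread = if (mean_total > 0) (max(totals) - min(totals)) / mean_total else 0
    ),
    class = "cost_simulation_result"
  )
}

#' @export
print.cost_simulation_result <- function(x, ...) {
  cat(sprintf("<cost_simulation_result> %s (%s)\n", x$scenario_label, x$schedule_label))
  cat(sprintf("  %d replications x %s women\n", x$n_replications,
              format(x$cohort_size, big.mark = ",")))
  cat(sprintf("  per woman: mean %.2f, sd %.2f\n",
              x$mean_cost_per_woman, x$sd_cost_per_woman))
  cat(sprintf("  total: mean %s [min %s, max %s], relative spread %.2e\n",
              format(round(x$mean_total), big.mark = ","),
              format(round(x$min_total), big.mark = ","),
              format(round(x$max_total), big.mark = ","), x$relative_spread))
  invisible(x)
}

#' Check replication reliability via relative spread
#'
#' The spread `(max - min) / mean` of replication totals measures simulation
#' reliability: for a well-behaved cohort simulation it should be a small
#' fraction of the mean.
#'
#' @param result A [simulate_cost_distribution()] result with at least 2
#'   replications.
#' @param threshold Maximum acceptable relative spread (default 0.002, i.e.
#'   0.2%).
#'
#' @return A list with `pass` (logical), `spread`, and `threshold`.
#' @export
relative_spread_check <- function(result, threshold = 0.002) {
  stopifnot(inherits(result, "cost_simulation_result"))
  if (result$n_replications < 2L) stop_("spread check needs >= 2 replications")
  list(pass = result$relative_spread < threshold,
       spread = result$relative_spread,
       threshold = threshold)
}
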