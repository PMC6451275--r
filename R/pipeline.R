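#' Load and validate a run configuration from YAML
#'
#' Reads a structured-text run configuration (field names carry explicit
#' units, e.g. `unit_costs_usd`, `*_pct`) and resolves defaults, echoing
#' each applied default to the log. Validation problems are reported
#' together as an itemised error listing field paths. A shipped
#' configuration equivalent to [rwanda_anc_inputs()] is available at
#' `system.file("extdata", "rwanda_anc.yaml", package = "anccea")`.
#'
#' @param path Path to a YAML configuration file.
#' @return An `anc_run_config` list (see [rwanda_anc_inputs()] for the
#'   structure).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  variant <- raw$variant %||% "replication"
  if (!variant %in% c("replication", "nominal")) {
    note("variant: must be 'replication' or 'nominal', got '%s'", variant)
  }

  schedules <- list()
  if (is.null(raw$schedules)) {
    note("schedules: at least one schedule is required")
  } else {
    for (i in seq_along(raw$schedules)) {
      s <- raw$schedules[[i]]
      lab <- s$label %||% sprintf("schedule-%d", i)
      sched <- tryCatch(
        visit_cost_schedule(lab, unlist(s$unit_costs_usd),
                            overflow_visit_cost = s$overflow_visit_cost_usd %||% 6),
        error = function(e) {
          note("schedules[%d] (%s): %s", i, lab, conditionMessage(e))
          NULL
        })
      if (!is.null(sched)) schedules[[lab]] <- sched
    }
  }

  parse_scenario <- function(sc, where, degenerate = FALSE) {
    tryCatch(
      attendance_scenario(sc$label %||% where,
                          mean_visits = sc$mean_visits,
                          sd_visits = sc$sd_visits %||% 0,
                          min_visits = sc$min_visits %||% sc$mean_visits,
                          max_visits = sc$max_visits %||% sc$mean_visits,
                          degenerate = degenerate),
      error = function(e) {
        note("%s: %s", where, conditionMessage(e))
        NULL
      })
  }
  check_schedule_ref <- function(ref, where) {
    if (is.null(ref) || !ref %in% names(schedules)) {
      note("%s: unknown schedule reference '%s'", where, ref %||% "<missing>")
      FALSE
    } else TRUE
  }

  costing <- list()
  labels_seen <- character(0)
  for (i in seq_along(raw$costing_scenarios)) {
    sc <- raw$costing_scenarios[[i]]
    where <- sprintf("costing_scenarios[%d]", i)
    scen <- parse_scenario(sc, where)
    ok <- check_schedule_ref(sc$schedule, where)
    if (!is.null(scen)) {
      if (scen$label %in% labels_seen) note("%s: duplicate label '%s'", where, scen$label)
      labels_seen <- c(labels_seen, scen$label)
    }
    if (!is.null(scen) && ok) {
      costing[[length(costing) + 1L]] <- list(
        scenario = scen, schedule = sc$schedule,
        published_total = sc$published_total_usd)
    }
  }
  if (!length(costing)) note("costing_scenarios: at least one scenario is required")

  full_util <- NULL
  if (!is.null(raw$full_utilisation)) {
    fu <- raw$full_utilisation
    where <- "full_utilisation"
    scen <- parse_scenario(fu, where, degenerate = TRUE)
    if (check_schedule_ref(fu$schedule, where) && !is.null(scen)) {
      full_util <- list(scenario = scen, schedule = fu$schedule,
                        published_total = fu$published_total_usd)
    }
  }

  out_sc <- NULL
  expert_csv <- NULL
  oc <- raw$outcomes
  if (is.null(oc)) {
    note("outcomes: required (expert_responses_csv or explicit reductions)")
  } else if (!is.null(oc$expert_responses_csv)) {
    expert_csv <- oc$expert_responses_csv
    if (!file.exists(expert_csv)) {
      expert_csv <- file.path(dirname(path), oc$expert_responses_csv)
    }
    if (!file.exists(expert_csv)) {
      note("outcomes.expert_responses_csv: file not found: %s", oc$expert_responses_csv)
    }
  } else {
    out_sc <- tryCatch(
      outcome_scenarios(unlist(oc$perinatal_reduction_pct),
                        unlist(oc$maternal_reduction_pct)),
      error = function(e) {
        note("outcomes: %s", conditionMessage(e))
        NULL
      })
  }

  b <- raw$baseline %||% list()
  discount <- b$discount_rate
  if (is.null(discount)) {
    discount <- 0.03
    message("load_run_config: baseline.discount_rate missing; default 0.03 applied")
  }
  horizon <- b$perinatal_discount_horizon_years %||%
    if (identical(variant, "replication")) 66 else 64
  mad <- b$maternal_age_distribution
  age_dist <- NULL
  if (is.null(mad)) {
    note("baseline.maternal_age_distribution: required")
  } else {
    mids <- unlist(mad$age_midpoint_years)
    if (!is.null(mad$share)) {
      age_dist <- data.frame(age_midpoint = mids, share = unlist(mad$share))
    } else if (!is.null(mad$base_share) &&
               !is.null(mad$target_discounted_years_per_death)) {
      age_dist <- tryCatch(
        calibrate_age_shares(unlist(mad$base_share), mids,
                             target_factor = mad$target_discounted_years_per_death,
                             life_expectancy_female = b$life_expectancy_female_years %||% 66,
                             discount_rate = discount),
        error = function(e) {
          note("baseline.maternal_age_distribution: %s", conditionMessage(e))
          NULL
        })
    } else {
      note("baseline.maternal_age_distribution: give either share or base_share + target_discounted_years_per_death")
    }
  }

  baseline <- NULL
  if (!is.null(age_dist)) {
    baseline <- tryCatch(
      baseline_epidemiology(
        annual_perinatal_deaths = b$annual_perinatal_deaths,
        annual_maternal_deaths = b$annual_maternal_deaths,
        life_expectancy_both_sexes = b$life_expectancy_both_sexes_years %||% 64,
        life_expectancy_female = b$life_expectancy_female_years %||% 66,
        discount_rate = discount,
        perinatal_discount_horizon_years = horizon,
        maternal_age_distribution = age_dist,
        perinatal_mortality_rate = b$perinatal_mortality_rate_per_1000 %||% NA_real_,
        maternal_mortality_ratio = b$maternal_mortality_ratio_per_100k %||% NA_real_
      ),
      error = function(e) {
        note("baseline: %s", conditionMessage(e))
        NULL
      })
  }

  cc <- raw$cea %||% list()
  cea <- tryCatch(
    cea_config(
      comparator_total_cost = cc$comparator_total_cost_usd %||% 13939970,
      comparator_cost_per_woman = cc$comparator_cost_per_woman_usd %||% 37,
      cohort_size = cc$cohort_size %||% 373679,
      gdp_per_capita = cc$gdp_per_capita_usd %||% 697
    ),
    error = function(e) {
      note("cea: %s", conditionMessage(e))
      NULL
    })

  seed <- raw$seed
  if (is.null(seed)) note("seed: required (simulations must be reproducible)")

  if (length(problems)) {
    stop_("invalid run configuration (%d problem%s):\n  - %s",
          length(problems), if (length(problems) > 1) "s" else "",
          paste(problems, collapse = "\n  - "))
  }
  message(sprintf("load_run_config: %s (variant %s, seed %s, %d replications)",
                  path, variant, seed, raw$n_replications %||% 100))

  structure(
    list(variant = variant, schedules = schedules, costing_scenarios = costing,
         full_utilisation = full_util,
         current_practice_survey = raw$current_practice_survey,
         outcome_scenarios = out_sc, expert_responses_csv = expert_csv,
         baseline = baseline, cea = cea,
         n_replications = raw$n_replications %||% 100,
         seed = as.integer(seed)),
    class = "anc_run_config"
  )
}

#' Run the full cost-effectiveness pipeline
#'
#' Executes attendance simulation, visit costing, outcome-scenario
#' construction, life-years-saved estimation and the ICER matrix for a run
#' configuration, optionally writing a report bundle (CSV tables, a
#' machine-readable JSON result with a run manifest, per-replication totals,
#' and a human-readable summary). Re-running with the same configuration and
#' seed reproduces the JSON report byte for byte.
#'
#' @param config An `anc_run_config` from [rwanda_anc_inputs()] or
#'   [load_run_config()].
#' @param out_dir Output directory for the report bundle, or `NULL` (no
#'   files written).
#' @param seed Master seed (defaults to the configured seed).
#' @param n_replications Replications per costing scenario (defaults to the
#'   configured value, normally 100).
#' @param cohort_size Cohort size (defaults to the configured value); reduce
#'   for quick exploratory runs.
#'
#' @return Invisibly, a list with the simulation results (`sims`,
#'   `full_utilisation`), `cost_table`, `gains`, `outcomes_table`,
#'   `cea_table`, `spread_checks`, and `manifest`.
#' @export
#' @examples
#' cfg <- rwanda_anc_inputs()
#' res <- run_pipeline(cfg, seed = 1, n_replications = 4, cohort_size = 5000)
#' res$cea_table
run_pipeline <- function(config, out_dir = NULL, seed = config$seed,
                         n_replications = config$n_replications,
                         cohort_size = config$cea$cohort_size) {
  stopifnot(inherits(config, "anc_run_config"))
  if (is.null(seed)) stop_("a seed is required")
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  message(sprintf("run_pipeline: variant=%s seed=%d replications=%d cohort=%d",
                  config$variant, as.integer(seed), n_replications, cohort_size))

  # one sub-seed per costing scenario, derived from the master seed
  set.seed(as.integer(seed))
  n_sims <- length(config$costing_scenarios) + 1L
  scenario_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)

  sims <- stage("attendance simulation + costing", {
    out <- list()
    for (i in seq_along(config$costing_scenarios)) {
      cs <- config$costing_scenarios[[i]]
      out[[cs$scenario$label]] <- simulate_cost_distribution(
        config$schedules[[cs$schedule]], cs$scenario, cohort_size,
        n_replications = n_replications, seed = scenario_seeds[i])
    }
    out
  })

  fu_sim <- NULL
  if (!is.null(config$full_utilisation)) {
    fu <- config$full_utilisation
    # degenerate: every replication identical, one is enough
    fu_sim <- simulate_cost_distribution(
      config$schedules[[fu$schedule]], fu$scenario, cohort_size,
      n_replications = 1, seed = scenario_seeds[n_sims])
  }

  cost_table <- stage("cost table", {
    comparator_total <- config$cea$comparator_total_cost
    full_comp_pw <- if (!is.null(config$full_utilisation)) {
      full_compliance_cost(config$schedules[[config$full_utilisation$schedule]])
    } else NA_real_
    row_of <- function(sim, published_total = NULL) {
      inc <- incremental_cost(sim$mean_total, comparator_total)
      flag <- !is.null(published_total) &&
        abs(sim$mean_total - published_total) / published_total > 0.01
      data.frame(
        scenario = sim$scenario_label,
        mean_cost_per_woman = sim$mean_cost_per_woman,
        sd_cost_per_woman = sim$sd_cost_per_woman,
        mean_total = sim$mean_total,
        min_total = sim$min_total,
        max_total = sim$max_total,
        incremental_total = inc,
        pct_increase = 100 * inc / comparator_total,
        incr_per_woman_vs_current = sim$mean_cost_per_woman -
          config$cea$comparator_cost_per_woman,
        incr_per_woman_vs_full_compliance = sim$mean_cost_per_woman - full_comp_pw,
        published_total = published_total %||% NA_real_,
        total_inconsistent_flag = flag,
        stringsAsFactors = FALSE
      )
    }
    rows <- list(data.frame(
      scenario = "current-practice",
      mean_cost_per_woman = config$cea$comparator_cost_per_woman,
      sd_cost_per_woman = NA_real_,
      mean_total = comparator_total, min_total = NA_real_, max_total = NA_real_,
      incremental_total = 0, pct_increase = 0,
      incr_per_woman_vs_current = 0,
      incr_per_woman_vs_full_compliance = config$cea$comparator_cost_per_woman -
        full_comp_pw,
      published_total = NA_real_, total_inconsistent_flag = FALSE,
      stringsAsFactors = FALSE))
    if (!is.null(fu_sim)) {
      rows[[length(rows) + 1L]] <-
        row_of(fu_sim, config$full_utilisation$published_total)
    }
    for (i in seq_along(config$costing_scenarios)) {
      cs <- config$costing_scenarios[[i]]
      rows[[length(rows) + 1L]] <-
        row_of(sims[[cs$scenario$label]], cs$published_total)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    for (i in which(tab$total_inconsistent_flag)) {
      message(sprintf(
        "[cost table] %s: simulated total %.0f deviates >1%% from published total %.0f; total-derived quantities flagged",
        tab$scenario[i], tab$mean_total[i], tab$published_total[i]))
    }
    tab
  })

  scenarios <- stage("outcome scenarios", {
    if (!is.null(config$expert_responses_csv)) {
      build_outcome_scenarios(
        merge_delphi_rounds(read_expert_responses(config$expert_responses_csv)))
    } else {
      config$outcome_scenarios
    }
  })
  if (is.null(scenarios)) stop_("no outcome scenarios available")

  gains <- stage("life-years saved", {
    out <- list()
    for (i in seq_len(nrow(scenarios))) {
      out[[scenarios$label[i]]] <- health_gains(config$baseline, scenarios[i, ])
    }
    out
  })

  outcomes_table <- do.call(rbind, lapply(gains, function(g) {
    data.frame(
      outcome_scenario = g$scenario_label,
      indicator = c("perinatal", "maternal"),
      reduction_pct = c(-g$perinatal_reduction_pct, -g$maternal_reduction_pct),
      deaths_averted = c(g$perinatal_deaths_averted, g$maternal_deaths_averted),
      lys = c(g$perinatal_lys, g$maternal_lys),
      total_lys = g$total_lys,
      stringsAsFactors = FALSE
    )
  }))
  rownames(outcomes_table) <- NULL

  cea_table <- stage("ICER matrix", build_cea_table(sims, gains, config$cea))
  for (i in seq_len(nrow(cea_table))) {
    message(sprintf("[cea] %s x %s: incremental $%.0f / %.0f LYS = $%.1f per LYS (%s)",
                    cea_table$costing_scenario[i], cea_table$outcome_scenario[i],
                    cea_table$incremental_cost[i], cea_table$lys[i],
                    cea_table$icer[i], cea_table$classification[i]))
  }

  spread_checks <- lapply(sims, function(s) {
    if (s$n_replications >= 2) relative_spread_check(s) else NULL
  })

  manifest <- list(
    package = "anccea",
    version = as.character(utils::packageVersion("anccea")),
    variant = config$variant,
    seed = as.integer(seed),
    n_replications = n_replications,
    cohort_size = cohort_size,
    perinatal_discount_horizon_years =
      config$baseline$perinatal_discount_horizon_years,
    discount_rate = config$baseline$discount_rate,
    gdp_per_capita = config$cea$gdp_per_capita,
    comparator_total_cost = config$cea$comparator_total_cost
  )

  bundle <- list(sims = sims, full_utilisation = fu_sim,
                 cost_table = cost_table, scenarios = scenarios, gains = gains,
                 outcomes_table = outcomes_table, cea_table = cea_table,
                 spread_checks = spread_checks, manifest = manifest)

  if (!is.null(out_dir)) {
    stage("write reports", write_report_bundle(bundle, out_dir))
  }
  invisible(bundle)
}

# Write the report bundle: CSV tables, per-replication totals, JSON results
# (deterministic for a fixed seed: no timestamps), and a plain-text summary.
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$cost_table, file.path(out_dir, "costs.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$outcomes_table, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$cea_table),
                   file.path(out_dir, "cea.csv"), row.names = FALSE)
  reps <- do.call(rbind, lapply(bundle$sims, function(s) {
    data.frame(scenario = s$scenario_label,
               replication = seq_len(s$n_replications),
               total_cost = s$total_cost_per_replication,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(reps, file.path(out_dir, "replication_totals.csv"),
                   row.names = FALSE)

  json <- list(
    manifest = bundle$manifest,
    cost_table = bundle$cost_table,
    outcome_scenarios = as.data.frame(bundle$scenarios),
    outcomes_table = bundle$outcomes_table,
    cea_table = as.data.frame(bundle$cea_table),
    spread_checks = lapply(bundle$spread_checks, function(x) {
      if (is.null(x)) NULL else x[c("spread", "threshold", "pass")]
    })
  )
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  summ <- c(
    sprintf("anccea run (variant %s, seed %d, %d replications, cohort %d)",
            bundle$manifest$variant, bundle$manifest$seed,
            bundle$manifest$n_replications, bundle$manifest$cohort_size),
    "",
    "Costing (USD):",
    sprintf("  %-32s per woman %6.2f  total %13.0f  incremental %12.0f (%+.0f%%)%s",
            bundle$cost_table$scenario, bundle$cost_table$mean_cost_per_woman,
            bundle$cost_table$mean_total, bundle$cost_table$incremental_total,
            round_half_up(bundle$cost_table$pct_increase),
            ifelse(bundle$cost_table$total_inconsistent_flag,
                   "  [total inconsistent with published figure]", "")),
    "",
    "Life-years saved (discounted):",
    sprintf("  %-12s %-10s %6.1f%%  %5d deaths averted  %9.0f LYS",
            bundle$outcomes_table$outcome_scenario,
            bundle$outcomes_table$indicator,
            bundle$outcomes_table$reduction_pct,
            bundle$outcomes_table$deaths_averted, bundle$outcomes_table$lys),
    "",
    "Incremental cost per life-year saved (USD):",
    sprintf("  %-32s x %-12s $%4.0f  %s",
            bundle$cea_table$costing_scenario, bundle$cea_table$outcome_scenario,
            bundle$cea_table$icer_rounded, bundle$cea_table$classification)
  )
  writeLines(summ, file.path(out_dir, "summary.txt"))
  invisible(NULL)
}
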