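# Run configuration for the Rwandan ANC cost-effectiveness analysis.
# All monetary fields are 2015 USD; field names carry explicit units.
variant: replication      # replication (perinatal horizon 66y) | nominal (64y)
seed: 20160101
n_replications: 100

schedules:
  - label: who-2016-eight-contact
    unit_costs_usd: [24, 6, 10, 6, 6, 10, 6, 11]
    overflow_visit_cost_usd: 6
  - label: current-practice-four-visit
    unit_costs_usd: [21, 6, 6, 11]
    overflow_visit_cost_usd: 6

costing_scenarios:
  - label: scenario-1-conservative
    schedule: who-2016-eight-contact
    mean_visits: 5
    sd_visits: 0.8
    min_visits: 1
    max_visits: 8
    published_total_usd: 19829260
  - label: scenario-2
    schedule: who-2016-eight-contact
    mean_visits: 6
    sd_visits: 0.8
    min_visits: 2
    max_visits: 10
    published_total_usd: 22799062
  - label: scenario-3-ambitious
    schedule: who-2016-eight-contact
    mean_visits: 7
    sd_visits: 0.8
    min_visits: 3
    max_visits: 11
    published_total_usd: 24895023

full_utilisation:
  label: full-utilisation-current-policy
  schedule: current-practice-four-visit
  mean_visits: 4

current_practice_survey:
  mean_visits: 3.3
  sd_visits: 0.8
  min_visits: 1
  max_visits: 8

outcomes:
  # two-round panel (synthetic stand-in for the elicitation records); the
  # merged half-splits give perinatal -22.5/-55 and maternal -7/-52.5
  expert_responses_csv: synthetic_expert_panel.csv

baseline:
  annual_perinatal_deaths: 10076
  annual_maternal_deaths: 371
  perinatal_mortality_rate_per_1000: 29
  maternal_mortality_ratio_per_100k: 210
  life_expectancy_both_sexes_years: 64
  life_expectancy_female_years: 66
  discount_rate: 0.03
  maternal_age_distribution:
    age_midpoint_years: [17.5, 22.5, 27.5, 32.5, 37.5, 42.5, 47.5]
    base_share: [0.08, 0.16, 0.22, 0.22, 0.17, 0.11, 0.04]
    # implied discounted years per maternal death (= 4044 / 195)
    target_discounted_years_per_death: 20.738461538461536

cea:
  comparator_total_cost_usd: 13939970
  comparator_cost_per_woman_usd: 37
  cohort_size: 373679
  gdp_per_capita_usd: 697
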