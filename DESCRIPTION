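Package: anccea
Title: Cost-Effectiveness Analysis of Expanded Antenatal Care Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Incremental cost-effectiveness analysis of an eight-contact
    antenatal care (ANC) schedule against a four-visit comparator, built for
    the Rwandan policy setting but fully configurable. Provides per-visit
    cost schedules, Monte Carlo simulation of ANC attendance for a national
    cohort with a closed-form costing oracle, aggregation of two-round
    (Delphi-style) expert panels into optimistic and pessimistic mortality
    reduction scenarios, conversion of mortality reductions into discounted
    life-years saved, and an incremental cost-effectiveness ratio (ICER)
    matrix classified against GDP-per-capita willingness-to-pay thresholds.
    Includes synthetic-data generators for attendance surveys and expert
    panels so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
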