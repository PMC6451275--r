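panel_csv <- system.file("extdata", "synthetic_expert_panel.csv",
                         package = "anccea")

test_that("round-2 responses supersede round 1; non-response confirms round 1", {
  resp <- data.frame(
    expert_id = c("A", "A", "B"),
    round = c(1, 2, 1),
    perinatal_reduction_pct = c(30, 40, 20),
    maternal_reduction_pct = c(10, 15, 5)
  )
  final <- merge_delphi_rounds(resp)
  expect_equal(nrow(final), 2)
  expect_equal(final$perinatal_reduction_pct[final$expert_id == "A"], 40)
  expect_equal(final$maternal_reduction_pct[final$expert_id == "B"], 5)
  expect_equal(final$source_round, c(2L, 1L))

  # idempotence: merging the merged estimates (as round-1 answers) changes nothing
  again <- merge_delphi_rounds(data.frame(
    expert_id = final$expert_id, round = 1L,
    perinatal_reduction_pct = final$perinatal_reduction_pct,
    maternal_reduction_pct = final$maternal_reduction_pct))
  expect_equal(again[, 1:3], final[, 1:3])
})

test_that("malformed panels are rejected", {
  base <- data.frame(expert_id = "A", round = 1,
                     perinatal_reduction_pct = 10, maternal_reduction_pct = 5)
  expect_error(merge_delphi_rounds(rbind(base, base)), "duplicate")
  orphan <- data.frame(expert_id = "B", round = 2,
                       perinatal_reduction_pct = 10, maternal_reduction_pct = 5)
  expect_error(merge_delphi_rounds(rbind(base, orphan)), "round-1")
  bad_pct <- base
  bad_pct$perinatal_reduction_pct <- 120
  expect_error(merge_delphi_rounds(bad_pct), "\\[0, 100\\]")
  expect_error(merge_delphi_rounds(base[, 1:3]), "missing column")
})

test_that("half-split means reproduce hand-computed scenario parameters", {
  expect_equal(split_half_means(c(10, 15, 25, 40, 45, 50, 60, 65)),
               c(pessimistic = 22.5, optimistic = 55))
  expect_equal(split_half_means(c(7, 7, 7, 7)),
               c(pessimistic = 7, optimistic = 7))
  expect_equal(split_half_means(c(0, 0, 100, 100)),
               c(pessimistic = 0, optimistic = 100))
  # odd panel: middle value joins the pessimistic half
  expect_equal(split_half_means(c(1, 2, 3)),
               c(pessimistic = 1.5, optimistic = 3))
  expect_equal(split_half_means(c(1, 2, 3), middle = "upper"),
               c(pessimistic = 1, optimistic = 2.5))
  expect_error(split_half_means(5), "at least 2")
})

test_that("splitting is order-invariant and brackets the overall mean", {
  set.seed(77)
  for (i in 1:10) {
    v <- runif(sample(2:11, 1), 0, 100)
    s <- split_half_means(v)
    expect_equal(split_half_means(sample(v)), s)
    expect_lte(s[["pessimistic"]], mean(v))
    expect_gte(s[["optimistic"]], mean(v))
    if (length(v) %% 2 == 0) {
      expect_equal(mean(s), mean(v))
    }
  }
})

test_that("the shipped two-round panel yields the elicited scenario parameters", {
  final <- merge_delphi_rounds(read_expert_responses(panel_csv))
  expect_equal(nrow(final), 8)
  expect_equal(sum(final$source_round == 2L), 7)  # one non-respondent
  sc <- build_outcome_scenarios(final)
  expect_equal(sc$perinatal_reduction_pct, c(22.5, 55))
  expect_equal(sc$maternal_reduction_pct, c(7, 52.5))
  expect_equal(sc$label, c("pessimistic", "optimistic"))
})

test_that("indicators are split independently and ids do not matter", {
  final <- merge_delphi_rounds(read_expert_responses(panel_csv))
  # an expert can sit in different halves for the two indicators
  peri_rank <- rank(final$perinatal_reduction_pct)
  mat_rank <- rank(final$maternal_reduction_pct)
  expect_false(all((peri_rank <= 4) == (mat_rank <= 4)))

  relabeled <- final
  relabeled$expert_id <- rev(sprintf("Z%02d", seq_len(nrow(final))))
  expect_equal(build_outcome_scenarios(relabeled)[, -1],
               build_outcome_scenarios(final)[, -1])
})

test_that("explicit outcome scenarios validate ordering and range", {
  sc <- outcome_scenarios(c(22.5, 55), c(7, 52.5))
  expect_s3_class(sc, "outcome_scenarios")
  expect_error(outcome_scenarios(c(55, 22.5), c(7, 52.5)), "optimistic")
  expect_error(outcome_scenarios(c(-5, 55), c(7, 52.5)), "\\[0, 100\\]")
})
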