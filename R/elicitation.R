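#' Validate a table of two-round expert responses
#'
#' Expert responses carry, per expert and elicitation round, the expected
#' percentage reduction in perinatal and maternal mortality if the
#' eight-contact schedule were implemented. Round 2 is a Delphi-style
#' revision after seeing the anonymised group response, so a round-2 row
#' requires a round-1 row for the same expert, and each (expert, round) pair
#' may appear at most once.
#'
#' @param responses A data frame with columns `expert_id`, `round` (1 or 2),
#'   `perinatal_reduction_pct` and `maternal_reduction_pct` (both in
#'   `[0, 100]`).
#' @return The validated data frame, invisibly coerced to canonical types.
#' @export
validate_expert_responses <- function(responses) {
  required <- c("expert_id", "round", "perinatal_reduction_pct",
                "maternal_reduction_pct")
  if (!is.data.frame(responses)) stop_("responses must be a data frame")
  missing <- setdiff(required, names(responses))
  if (length(missing)) {
    stop_("responses is missing column(s): %s", paste(missing, collapse = ", "))
  }
  responses$expert_id <- as.character(responses$expert_id)
  responses$round <- as.integer(responses$round)
  if (anyNA(responses$round) || !all(responses$round %in% c(1L, 2L))) {
    stop_("round must be 1 or 2")
  }
  for (col in c("perinatal_reduction_pct", "maternal_reduction_pct")) {
    v <- responses[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 100)) {
      stop_("%s must be numeric in [0, 100]", col)
    }
  }
  key <- paste(responses$expert_id, responses$round)
  if (anyDuplicated(key)) {
    stop_("duplicate response for (expert, round): %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  r2 <- responses$expert_id[responses$round == 2L]
  r1 <- responses$expert_id[responses$round == 1L]
  orphan <- setdiff(r2, r1)
  if (length(orphan)) {
    stop_("round-2 response without a round-1 response for expert(s): %s",
          paste(orphan, collapse = ", "))
  }
  responses
}

#' Merge two Delphi rounds into one final estimate per expert
#'
#' Round-2 responses supersede round-1 responses; an expert with no round-2
#' row keeps their round-1 values (non-response is taken as confirmation of
#' the initial estimate). The merge is idempotent.
#'
#' @inheritParams validate_expert_responses
#' @return A data frame with one row per expert: `expert_id`,
#'   `perinatal_reduction_pct`, `maternal_reduction_pct`, and `source_round`
#'   (the round the final values came from), ordered by `expert_id`.
#' @export
#' @examples
#' resp <- data.frame(
#'   expert_id = c("A", "A", "B"), round = c(1, 2, 1),
#'   perinatal_reduction_pct = c(30, 40, 20),
#'   maternal_reduction_pct = c(10, 15, 5)
#' )
#' merge_delphi_rounds(resp)
merge_delphi_rounds <- function(responses) {
  responses <- validate_expert_responses(responses)
  # within each expert keep the highest round
  ord <- order(responses$expert_id, -responses$round)
  responses <- responses[ord, , drop = FALSE]
  keep <- !duplicated(responses$expert_id)
  out <- responses[keep, c("expert_id", "perinatal_reduction_pct",
                           "maternal_reduction_pct", "round")]
  names(out)[names(out) == "round"] <- "source_round"
  out <- out[order(out$expert_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split one indicator's final estimates into pessimistic and optimistic means
#'
#' Orders the estimates ascending and divides them into two halves; the mean
#' of the lower half is the pessimistic scenario parameter, the mean of the
#' upper half the optimistic one. For an odd number of estimates the middle
#' value joins the lower (pessimistic) half, a conservative convention.
#'
#' @param values Numeric vector of at least 2 percentage estimates.
#' @param middle Where the middle value goes for odd counts: `"lower"`
#'   (default, conservative) or `"upper"`.
#' @return Named numeric vector `c(pessimistic = , optimistic = )`.
#' @export
#' @examples
#' split_half_means(c(10, 15, 25, 40, 45, 50, 60, 65)) # 22.5 / 55
split_half_means <- function(values, middle = c("lower", "upper")) {
  middle <- match.arg(middle)
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    stop_("need at least 2 non-missing values to split")
  }
  sorted <- sort(values)  # stable; ties keep input order
  n <- length(sorted)
  m <- if (middle == "lower") ceiling(n / 2) else floor(n / 2)
  c(pessimistic = mean(sorted[seq_len(m)]),
    optimistic = mean(sorted[(m + 1L):n]))
}

#' Build the optimistic and pessimistic outcome scenarios from a panel
#'
#' Applies [split_half_means()] independently to the perinatal and maternal
#' indicator columns of the merged panel (an expert may fall in the lower
#' half for one indicator and the upper half for the other). Ties at the
#' split boundary are resolved by a stable sort on (value, expert order), so
#' the result is deterministic and invariant to row order.
#'
#' @param final_estimates A data frame as returned by
#'   [merge_delphi_rounds()] (>= 2 experts).
#' @param middle Passed to [split_half_means()].
#' @return A data frame of class `outcome_scenarios` with rows
#'   `pessimistic` and `optimistic` and columns `label`,
#'   `perinatal_reduction_pct`, `maternal_reduction_pct`. Reductions are
#'   stored as positive percentages; the direction (mortality decrease) is
#'   applied downstream.
#' @export
build_outcome_scenarios <- function(final_estimates, middle = "lower") {
  stopifnot(is.data.frame(final_estimates))
  if (nrow(final_estimates) < 2L) stop_("need at least 2 experts")
  peri <- split_half_means(final_estimates$perinatal_reduction_pct, middle)
  mat <- split_half_means(final_estimates$maternal_reduction_pct, middle)
  out <- data.frame(
    label = c("pessimistic", "optimistic"),
    perinatal_reduction_pct = c(peri[["pessimistic"]], peri[["optimistic"]]),
    maternal_reduction_pct = c(mat[["pessimistic"]], mat[["optimistic"]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("outcome_scenarios", "data.frame")
  out
}

#' Explicitly specified outcome scenarios
#'
#' Constructs the same object as [build_outcome_scenarios()] from known
#' scenario parameters instead of a panel.
#'
#' @param perinatal_pct Length-2 numeric `c(pessimistic, optimistic)`
#'   perinatal mortality reductions (%).
#' @param maternal_pct Length-2 numeric `c(pessimistic, optimistic)`
#'   maternal mortality reductions (%).
#' @return An `outcome_scenarios` data frame.
#' @export
outcome_scenarios <- function(perinatal_pct, maternal_pct) {
  stopifnot(length(perinatal_pct) == 2L, length(maternal_pct) == 2L)
  if (any(c(perinatal_pct, maternal_pct) < 0 | c(perinatal_pct, maternal_pct) > 100)) {
    stop_("reductions must be percentages in [0, 100]")
  }
  if (perinatal_pct[2L] < perinatal_pct[1L] || maternal_pct[2L] < maternal_pct[1L]) {
    stop_("optimistic reduction must be >= pessimistic reduction for each indicator")
  }
  out <- data.frame(
    label = c("pessimistic", "optimistic"),
    perinatal_reduction_pct = as.numeric(perinatal_pct),
    maternal_reduction_pct = as.numeric(maternal_pct),
    stringsAsFactors = FALSE
  )
  class(out) <- c("outcome_scenarios", "data.frame")
  out
}

#' Read expert responses from CSV
#'
#' @param path CSV file with columns `expert_id`, `round`,
#'   `perinatal_reduction_pct`, `maternal_reduction_pct`.
#' @return Validated responses data frame.
#' @export
read_expert_responses <- function(path) {
  if (!file.exists(path)) stop_("expert response file not found: %s", path)
  validate_expert_responses(utils::read.csv(path, stringsAsFactors = FALSE))
}
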