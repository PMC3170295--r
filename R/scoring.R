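#' Score the Siegrist effort scale
#'
#' Sum of the 6 effort item responses (each rated 1--5); the result lies in
#' \[6, 30\].
#'
#' @param responses Integer vector of exactly 6 responses in \[1, 5\].
#' @return Integer effort score.
#' @export
#' @examples
#' score_effort(c(1, 2, 3, 4, 5, 5))
score_effort <- function(responses) {
  check_responses(responses, n = 6L, min_level = 1L, max_level = 5L,
                  what = "effort")
  as.integer(sum(responses))
}

#' Score the Siegrist reward scale
#'
#' Sum of the 11 reward item responses.  Responses are expected
#' post-recoding, i.e. on a 1--5 scale where 5 is the most favourable
#' (highest-reward) answer; the result lies in \[11, 55\].
#'
#' @param responses Integer vector of exactly 11 responses in \[1, 5\].
#' @return Integer reward score.
#' @export
score_reward <- function(responses) {
  check_responses(responses, n = 11L, min_level = 1L, max_level = 5L,
                  what = "reward")
  as.integer(sum(responses))
}

#' Score the GHQ-12 (Likert method)
#'
#' Sum of the 12 GHQ item responses on the 0--3 Likert scoring; the result
#' lies in \[0, 36\].  Higher scores indicate worse self-reported mental
#' health.
#'
#' @param responses Integer vector of exactly 12 responses in \[0, 3\].
#' @return Integer GHQ-12 Likert score.
#' @export
score_ghq <- function(responses) {
  check_responses(responses, n = 12L, min_level = 0L, max_level = 3L,
                  what = "GHQ")
  as.integer(sum(responses))
}

#' @keywords internal
check_responses <- function(responses, n, min_level, max_level, what) {
  if (length(responses) != n) {
    stop(sprintf("expected exactly %d %s responses, got %d",
                 n, what, length(responses)), call. = FALSE)
  }
  if (anyNA(responses) || any(responses != round(responses)) ||
      any(responses < min_level) || any(responses > max_level)) {
    stop(sprintf("%s responses must be integers in [%d, %d]",
                 what, min_level, max_level), call. = FALSE)
  }
  invisible(responses)
}

#' Effort-reward imbalance ratio
#'
#' `effort / (reward * 6/11)`.  The 6/11 correction factor rescales the
#' reward score to compensate for the unequal item counts (6 effort vs 11
#' reward items), so a subject answering every item at the same level gets a
#' ratio of exactly 1.
#'
#' @param effort Effort score(s) in \[6, 30\].
#' @param reward Reward score(s) in \[11, 55\].
#' @return The imbalance ratio (dimensionless, > 0); values above 1 indicate
#'   high effort relative to reward.
#' @export
#' @examples
#' eri_ratio(6, 11)   # balanced minimum -> 1
#' eri_ratio(12, 44)  # 0.5
eri_ratio <- function(effort, reward) {
  if (any(effort < 6 | effort > 30) || any(reward < 11 | reward > 55)) {
    stop("effort must be in [6, 30] and reward in [11, 55]", call. = FALSE)
  }
  effort / (reward * (6 / 11))
}

#' Log-transformed imbalance ratio
#'
#' Natural logarithm of the ERI ratio.  The transform places reciprocal
#' imbalances of equal magnitude symmetrically about zero:
#' `log_eri_ratio(r) == -log_eri_ratio(1/r)`.
#'
#' @param ratio Positive ratio value(s).
#' @return Natural log of the ratio.
#' @export
log_eri_ratio <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be positive and finite", call. = FALSE)
  }
  log(ratio)
}

#' Log-transformed GHQ score
#'
#' Natural logarithm of `score + offset`.  The default offset is 0; a score
#' of exactly 0 (all 12 items at level 0) then has no finite log, and this
#' function signals an error.  Population-level scoring
#' ([score_population()]) falls back to an offset of 1 for such populations.
#'
#' @param score GHQ-12 Likert score(s) in \[0, 36\].
#' @param offset Non-negative constant added before taking the log.
#' @return Natural log of `score + offset`.
#' @export
log_ghq <- function(score, offset = 0) {
  if (any(score < 0) || offset < 0) {
    stop("score and offset must be non-negative", call. = FALSE)
  }
  if (offset == 0 && any(score == 0)) {
    stop("log_ghq undefined for score 0 with offset 0; use a positive offset",
         call. = FALSE)
  }
  log(score + offset)
}

#' Score every subject of a simulated population
#'
#' Applies the five scoring operations column-block-wise to a subjects x
#' items response matrix whose column order matches `item_specs`.
#'
#' With `log_offset = 0` a GHQ score of exactly 0 would have no finite log;
#' populations containing such a subject are scored with an offset of 1
#' instead (with a warning), and the fallback is recorded in the
#' `ghq_log_offset` attribute of the result.
#'
#' @param responses Integer matrix, subjects in rows, 29 item columns in the
#'   order of `item_specs`.
#' @param item_specs Item specification data frame; see
#'   [default_item_specs()].
#' @param log_offset Offset used by [log_ghq()]; default 0.
#' @return A data frame with one row per subject and columns `effort`,
#'   `reward`, `eri_ratio`, `log_eri_ratio`, `ghq` and `log_ghq`.
#' @export
score_population <- function(responses, item_specs = default_item_specs(),
                             log_offset = 0) {
  item_specs <- validate_item_specs(item_specs)
  responses <- validate_population(responses, item_specs)

  effort <- as.integer(rowSums(responses[, item_specs$instrument == "ERI_EFFORT",
                                         drop = FALSE]))
  reward <- as.integer(rowSums(responses[, item_specs$instrument == "ERI_REWARD",
                                         drop = FALSE]))
  ghq <- as.integer(rowSums(responses[, item_specs$instrument == "GHQ",
                                      drop = FALSE]))
  ratio <- eri_ratio(effort, reward)

  offset_used <- log_offset
  if (log_offset == 0 && any(ghq == 0)) {
    warning("GHQ score of 0 encountered with log offset 0; ",
            "falling back to offset 1 for this population")
    offset_used <- 1
  }
  out <- data.frame(
    effort = effort,
    reward = reward,
    eri_ratio = ratio,
    log_eri_ratio = log_eri_ratio(ratio),
    ghq = ghq,
    log_ghq = log_ghq(ghq, offset = offset_used)
  )
  attr(out, "ghq_log_offset") <- offset_used
  out
}

#' @keywords internal
validate_population <- function(responses, item_specs) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses) || !is.numeric(responses)) {
    stop("responses must be a numeric matrix", call. = FALSE)
  }
  if (nrow(responses) < 1L) {
    stop("responses must contain at least one subject", call. = FALSE)
  }
  if (ncol(responses) != nrow(item_specs)) {
    stop(sprintf("response matrix has %d columns but item specification has %d items",
                 ncol(responses), nrow(item_specs)), call. = FALSE)
  }
  if (!is.null(colnames(responses)) &&
      !identical(colnames(responses), item_specs$item_id)) {
    stop("response matrix column names do not match item specification order",
         call. = FALSE)
  }
  lo <- matrix(item_specs$min_level, nrow(responses), ncol(responses), byrow = TRUE)
  hi <- matrix(item_specs$max_level, nrow(responses), ncol(responses), byrow = TRUE)
  if (anyNA(responses) || any(responses != round(responses)) ||
      any(responses < lo) || any(responses > hi)) {
    stop("response matrix contains values outside the item response ranges",
         call. = FALSE)
  }
  storage.mode(responses) <- "integer"
  responses
}
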