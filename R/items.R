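#' Canonical questionnaire item specification
#'
#' Returns the 29-item layout used throughout the package: 6 Siegrist effort
#' items, 11 Siegrist reward items (5 esteem, 4 job promotion, 2 job
#' security) and 12 GHQ-12 items.  ERI items are rated 1--5 (reward items
#' stored post-recoding, 5 = most reward); GHQ items use the 0--3 Likert
#' scoring.  `negative_direction` gives the sign of the one-level shift a
#' negative-affectivity (NA) response takes: +1 for effort and GHQ items
#' (more distress / more symptoms), -1 for reward items (less reward).
#'
#' @return A data frame with one row per item and columns `item_id`,
#'   `instrument` (`"ERI_EFFORT"`, `"ERI_REWARD"` or `"GHQ"`), `subscale`
#'   (`"NONE"`, `"ESTEEM"`, `"PROMOTION"` or `"SECURITY"`), `min_level`,
#'   `max_level` and `negative_direction`.
#' @seealso [read_item_specs()] to load a custom layout from CSV.
#' @export
#' @examples
#' specs <- default_item_specs()
#' table(specs$instrument)
default_item_specs <- function() {
  specs <- rbind(
    data.frame(
      item_id = sprintf("effort_%d", 1:6),
      instrument = "ERI_EFFORT", subscale = "NONE",
      min_level = 1L, max_level = 5L, negative_direction = 1L
    ),
    data.frame(
      item_id = c(sprintf("esteem_%d", 1:5),
                  sprintf("promotion_%d", 1:4),
                  sprintf("security_%d", 1:2)),
      instrument = "ERI_REWARD",
      subscale = rep(c("ESTEEM", "PROMOTION", "SECURITY"), c(5L, 4L, 2L)),
      min_level = 1L, max_level = 5L, negative_direction = -1L
    ),
    data.frame(
      item_id = sprintf("ghq_%d", 1:12),
      instrument = "GHQ", subscale = "NONE",
      min_level = 0L, max_level = 3L, negative_direction = 1L
    )
  )
  validate_item_specs(specs)
}

#' @keywords internal
validate_item_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  required <- c("item_id", "instrument", "subscale",
                "min_level", "max_level", "negative_direction")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0) {
    stop("item specification is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(specs$item_id)) {
    stop("duplicated item_id in item specification", call. = FALSE)
  }
  if (!all(specs$instrument %in% c("ERI_EFFORT", "ERI_REWARD", "GHQ"))) {
    stop("unknown instrument in item specification", call. = FALSE)
  }
  n_inst <- table(factor(specs$instrument,
                         levels = c("ERI_EFFORT", "ERI_REWARD", "GHQ")))
  if (n_inst[["ERI_EFFORT"]] != 6L || n_inst[["ERI_REWARD"]] != 11L ||
      n_inst[["GHQ"]] != 12L) {
    stop("expected 6 effort, 11 reward and 12 GHQ items; got ",
         paste(n_inst, collapse = "/"), call. = FALSE)
  }
  reward_sub <- table(factor(specs$subscale[specs$instrument == "ERI_REWARD"],
                             levels = c("ESTEEM", "PROMOTION", "SECURITY")))
  if (reward_sub[["ESTEEM"]] != 5L || reward_sub[["PROMOTION"]] != 4L ||
      reward_sub[["SECURITY"]] != 2L) {
    stop("reward subscales must partition as 5 esteem + 4 promotion + 2 security",
         call. = FALSE)
  }
  eri <- specs$instrument != "GHQ"
  if (!all(specs$min_level[eri] == 1L & specs$max_level[eri] == 5L)) {
    stop("ERI items must use the 1-5 response range", call. = FALSE)
  }
  if (!all(specs$min_level[!eri] == 0L & specs$max_level[!eri] == 3L)) {
    stop("GHQ items must use the 0-3 scored range", call. = FALSE)
  }
  expected_dir <- ifelse(specs$instrument == "ERI_REWARD", -1L, 1L)
  if (!all(specs$negative_direction == expected_dir)) {
    stop("negative_direction must be +1 for effort/GHQ items and -1 for reward items",
         call. = FALSE)
  }
  specs
}

#' Read or write an item specification CSV
#'
#' The on-disk format has exactly the columns of [default_item_specs()].
#' A canonical copy ships with the package under
#' `system.file("extdata", "item_specs.csv", package = "nabiassim")`.
#'
#' @param path Path to a CSV file.
#' @param specs An item specification data frame.
#' @return `read_item_specs()` returns a validated item specification data
#'   frame; `write_item_specs()` returns `path` invisibly.
#' @export
read_item_specs <- function(path) {
  specs <- utils::read.csv(path, stringsAsFactors = FALSE)
  specs$min_level <- as.integer(specs$min_level)
  specs$max_level <- as.integer(specs$max_level)
  specs$negative_direction <- as.integer(specs$negative_direction)
  validate_item_specs(specs)
}

#' @rdname read_item_specs
#' @export
write_item_specs <- function(specs, path) {
  validate_item_specs(specs)
  utils::write.csv(specs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
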