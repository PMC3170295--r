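#' Negative-affectivity bias configuration
#'
#' The bias mechanism has two knobs: `p_subject`, the probability that a
#' subject carries the NA trait, and `q_items`, the per-item probability
#' that an NA subject's response to that item is influenced.  Either knob at
#' 0 reduces the mechanism to the identity (the unbiased baseline).
#'
#' @param p_subject Probability in \[0, 1\] that a subject displays NA.
#' @param q_items Probability in \[0, 1\] that an item of an NA subject is
#'   affected.
#' @return A list with class `"na_config"`.
#' @export
#' @examples
#' na_config(0.10, 0.30)
na_config <- function(p_subject, q_items) {
  if (length(p_subject) != 1 || length(q_items) != 1 ||
      p_subject < 0 || p_subject > 1 || q_items < 0 || q_items > 1) {
    stop("p_subject and q_items must be single values in [0, 1]", call. = FALSE)
  }
  structure(list(p_subject = p_subject, q_items = q_items),
            class = "na_config")
}

#' Sample which subjects display negative affectivity
#'
#' Independent Bernoulli(`p_subject`) draw per subject, consuming
#' `n_subjects` uniforms from R's global stream.  A subject is flagged when
#' its uniform falls below `p_subject`, so with a shared stream the flagged
#' set grows monotonically in `p_subject`.
#'
#' @param n_subjects Number of subjects.
#' @param p_subject NA prevalence in \[0, 1\].
#' @return Logical vector of length `n_subjects`.
#' @export
sample_na_mask <- function(n_subjects, p_subject) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (p_subject < 0 || p_subject > 1) {
    stop("p_subject must be in [0, 1]", call. = FALSE)
  }
  stats::runif(n_subjects) < p_subject
}

#' Sample the items influenced by NA for one subject
#'
#' Each item is included independently with probability `q_items`, so the
#' affected fraction equals `q_items` on average rather than exactly.
#'
#' @param item_specs Item specification data frame.
#' @param q_items Per-item inclusion probability in \[0, 1\].
#' @return Character vector of affected `item_id`s.
#' @export
select_affected_items <- function(item_specs = default_item_specs(), q_items) {
  if (q_items < 0 || q_items > 1) {
    stop("q_items must be in [0, 1]", call. = FALSE)
  }
  item_specs$item_id[stats::runif(nrow(item_specs)) < q_items]
}

#' Shift one response to its next "negative" value
#'
#' Moves the response one level in the item's negative direction — up for
#' effort and GHQ items (more distress, more symptoms), down for reward
#' items (less reward) — saturating at the scale boundary: the next negative
#' value of an already-most-negative response is itself.
#'
#' @param value Integer response within the item's range.
#' @param spec One row of an item specification data frame.
#' @return The shifted integer response.
#' @export
#' @examples
#' specs <- default_item_specs()
#' shift_negative(3, specs[specs$instrument == "ERI_EFFORT", ][1, ])  # 4
#' shift_negative(2, specs[specs$instrument == "ERI_REWARD", ][1, ])  # 1
shift_negative <- function(value, spec) {
  if (any(value < spec$min_level) || any(value > spec$max_level)) {
    stop("value outside the item's response range", call. = FALSE)
  }
  as.integer(pmin(pmax(value + spec$negative_direction, spec$min_level),
                  spec$max_level))
}

#' Inject negative-affectivity bias into a population
#'
#' For each subject flagged by an independent Bernoulli(`p_subject`) draw,
#' an independent affected-item set is drawn (each item with probability
#' `q_items`) and every affected cell is shifted one level in its item's
#' negative direction, saturating at the boundary.  All other cells are
#' unchanged; the input matrix is not modified.
#'
#' The full `n + n * 29` uniforms (subject draws, then item draws for every
#' subject) are consumed regardless of `p_subject` and `q_items`.  Starting
#' from the same RNG state, the set of shifted cells therefore grows
#' monotonically in both knobs — shared-random-number coupling across the
#' bias grid.
#'
#' @param pop Subjects x items integer response matrix.
#' @param config An [na_config()].
#' @param item_specs Item specification data frame.
#' @return A new response matrix of the same shape.
#' @export
inject_na <- function(pop, config, item_specs = default_item_specs()) {
  item_specs <- validate_item_specs(item_specs)
  pop <- validate_population(pop, item_specs)
  stopifnot(inherits(config, "na_config"))
  n <- nrow(pop)
  m <- ncol(pop)
  u_subject <- stats::runif(n)
  u_item <- matrix(stats::runif(n * m), n, m)
  affected <- (u_subject < config$p_subject) & (u_item < config$q_items)
  dir <- matrix(item_specs$negative_direction, n, m, byrow = TRUE)
  lo <- matrix(item_specs$min_level, n, m, byrow = TRUE)
  hi <- matrix(item_specs$max_level, n, m, byrow = TRUE)
  out <- pmin(pmax(pop + affected * dir, lo), hi)
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(pop)
  out
}
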