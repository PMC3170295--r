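#' @keywords internal
validate_marginal_table <- function(marginals, item_specs) {
  stopifnot(is.data.frame(marginals))
  required <- c("item_id", "level", "probability")
  if (!all(required %in% names(marginals))) {
    stop("marginal table needs columns item_id, level, probability", call. = FALSE)
  }
  if (!setequal(unique(marginals$item_id), item_specs$item_id)) {
    stop("marginal table must cover all items of the specification exactly once",
         call. = FALSE)
  }
  for (i in seq_len(nrow(item_specs))) {
    rows <- marginals[marginals$item_id == item_specs$item_id[i], ]
    support <- item_specs$min_level[i]:item_specs$max_level[i]
    if (!identical(sort(rows$level), as.numeric(support)) &&
        !identical(sort(as.integer(rows$level)), as.integer(support))) {
      stop(sprintf("item '%s': marginal support does not match the [%d, %d] range",
                   item_specs$item_id[i], item_specs$min_level[i],
                   item_specs$max_level[i]), call. = FALSE)
    }
    p <- rows$probability
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(sprintf("item '%s': probabilities must be non-negative and sum to 1",
                   item_specs$item_id[i]), call. = FALSE)
    }
  }
  marginals
}

#' Estimate item-level marginal distributions from observed responses
#'
#' Computes, for every item, the empirical relative frequency of each
#' response level over the item's full support (levels never observed get
#' probability 0).  These per-item marginals are the complete population
#' model of the simulation: items are later sampled independently, which
#' erases any true association between the scales (the null hypothesis).
#'
#' @param responses Subjects x items integer matrix, columns ordered as in
#'   `item_specs`.
#' @param item_specs Item specification data frame.
#' @return A marginal table: long-format data frame with columns `item_id`,
#'   `level`, `probability`.
#' @export
estimate_marginals <- function(responses, item_specs = default_item_specs()) {
  item_specs <- validate_item_specs(item_specs)
  responses <- validate_population(responses, item_specs)
  out <- lapply(seq_len(nrow(item_specs)), function(i) {
    support <- item_specs$min_level[i]:item_specs$max_level[i]
    counts <- tabulate(responses[, i] - item_specs$min_level[i] + 1L,
                       nbins = length(support))
    data.frame(item_id = item_specs$item_id[i], level = support,
               probability = counts / nrow(responses))
  })
  do.call(rbind, out)
}

#' @keywords internal
#' Bin probabilities of a normal(mu, sigma) discretized onto consecutive
#' integer levels, truncated to [min - 0.5, max + 0.5].  Upper-tail pnorm is
#' used on the right of the mean to avoid cancellation.
discretized_truncnorm <- function(mu, sigma, levels) {
  cuts <- c(levels[1] - 0.5, levels + 0.5)
  z <- (cuts - mu) / sigma
  mass <- ifelse(z[-length(z)] > 0,
                 stats::pnorm(z[-length(z)], lower.tail = FALSE) -
                   stats::pnorm(z[-1], lower.tail = FALSE),
                 stats::pnorm(z[-1]) - stats::pnorm(z[-length(z)]))
  mass[mass < 0] <- 0
  total <- sum(mass)
  if (total <= 0) {
    # mu so far outside the support that every bin underflows: fall back to
    # the log-space density tilt, which preserves the relative weights
    loglik <- -(levels - mu)^2 / (2 * sigma^2)
    mass <- exp(loglik - max(loglik))
    total <- sum(mass)
  }
  mass / total
}

#' Calibrate one item's marginal distribution to target moments
#'
#' Finds a categorical distribution on the integer levels
#' `min_level..max_level` whose mean and standard deviation match the
#' targets.  The two-parameter family used is the discretized truncated
#' normal: bin the normal(mu, sigma) density at half-integer cut points,
#' truncate to the support, and solve (mu, sigma) from the two moment
#' equations by nested root finding (mu by bisection inside each sigma
#' evaluation, sigma by bisection on the matched-mean SD).
#'
#' The truncated-normal family is log-concave, so its attainable SD at a
#' given mean is bounded: below by the two-adjacent-level distribution and
#' above by its large-sigma (geometric-tilt) limit.  A target SD above that
#' limit but within the absolute two-point bound
#' `sqrt((mean - min)(max - mean))` is met exactly by mixing the
#' mean-matched tilt with the mean-matched two-point boundary distribution
#' (the mixture variance is linear in the weight).  Targets outside the
#' absolute bounds raise a calibration error naming the violated bound.
#'
#' @param target_mean Desired mean, strictly inside `(min_level, max_level)`.
#' @param target_sd Desired standard deviation (> 0).
#' @param min_level,max_level Integer support bounds.
#' @param mean_tol,sd_tol Acceptance tolerances for the achieved moments.
#' @return Named numeric probability vector over the support, names are the
#'   levels.
#' @export
#' @examples
#' p <- calibrate_item_marginal(2.0833, 0.7757, 1, 5)
#' sum(p * (1:5))  # ~ 2.0833
calibrate_item_marginal <- function(target_mean, target_sd, min_level, max_level,
                                    mean_tol = 1e-6, sd_tol = 1e-4) {
  stopifnot(min_level < max_level)
  levels <- min_level:max_level
  if (target_mean <= min_level || target_mean >= max_level) {
    stop("calibration error: target_mean must lie strictly inside the level range",
         call. = FALSE)
  }
  if (target_sd < 0) {
    stop("calibration error: target_sd must be non-negative", call. = FALSE)
  }
  max_sd <- sqrt((target_mean - min_level) * (max_level - target_mean))
  if (target_sd > max_sd) {
    stop(sprintf(paste0("calibration error: target_sd %.4f exceeds the maximum ",
                        "%.4f attainable with mean %.4f on [%d, %d]"),
                 target_sd, max_sd, target_mean, min_level, max_level),
         call. = FALSE)
  }

  moments <- function(p) {
    m <- sum(p * levels)
    v <- sum(p * levels^2) - m^2
    c(mean = m, sd = sqrt(max(v, 0)))
  }

  # degenerate target: (near-)zero SD is a point mass, only valid at a level
  if (target_sd < 1e-6) {
    nearest <- levels[which.min(abs(levels - target_mean))]
    if (abs(nearest - target_mean) > mean_tol) {
      stop("calibration error: target_sd ~ 0 requires an integer target_mean",
           call. = FALSE)
    }
    p <- as.numeric(levels == nearest)
    names(p) <- levels
    return(p)
  }

  solve_mu <- function(sigma) {
    # the discretized family is an exponential tilt with natural parameter
    # mu/sigma^2, so pushing the mean to the boundary needs mu ~ sigma^2
    span <- 10 * sigma * max(1, sigma) + (max_level - min_level)
    stats::uniroot(
      function(mu) sum(discretized_truncnorm(mu, sigma, levels) * levels) -
        target_mean,
      lower = min_level - span, upper = max_level + span, tol = 1e-12
    )$root
  }
  sd_err <- function(sigma) {
    p <- discretized_truncnorm(solve_mu(sigma), sigma, levels)
    moments(p)[["sd"]] - target_sd
  }

  sig_lo <- 0.05
  sig_hi <- 500
  err_lo <- sd_err(sig_lo)
  err_hi <- sd_err(sig_hi)
  if (err_lo > 0) {
    # target below the family's minimum SD at this mean
    if (err_lo > sd_tol) {
      stop(sprintf(paste0("calibration error: target_sd %.4f is below the minimum ",
                          "%.4f attainable at mean %.4f"),
                   target_sd, err_lo + target_sd, target_mean), call. = FALSE)
    }
    sigma <- sig_lo
  } else if (err_hi < 0) {
    if (-err_hi > sd_tol) {
      # target above the truncated-normal family's maximum SD at this mean
      # (its large-sigma limit is a geometric tilt).  Mix the mean-matched
      # tilt with the mean-matched two-point boundary distribution; the
      # mixture variance is linear in the weight, so the solve is exact.
      p_base <- discretized_truncnorm(solve_mu(sig_hi), sig_hi, levels)
      p_ext <- numeric(length(levels))
      p_ext[length(levels)] <- (target_mean - min_level) / (max_level - min_level)
      p_ext[1] <- 1 - p_ext[length(levels)]
      var_base <- sum(p_base * levels^2) - target_mean^2
      var_ext <- sum(p_ext * levels^2) - target_mean^2
      w <- (target_sd^2 - var_base) / (var_ext - var_base)
      p <- (1 - w) * p_base + w * p_ext
      names(p) <- levels
      return(p)
    }
    sigma <- sig_hi
  } else {
    sigma <- stats::uniroot(sd_err, c(sig_lo, sig_hi), tol = 1e-10)$root
  }

  p <- discretized_truncnorm(solve_mu(sigma), sigma, levels)
  got <- moments(p)
  if (abs(got[["mean"]] - target_mean) > mean_tol ||
      abs(got[["sd"]] - target_sd) > sd_tol) {
    stop(sprintf("calibration failed to converge: achieved mean %.6f sd %.6f",
                 got[["mean"]], got[["sd"]]), call. = FALSE)
  }
  names(p) <- levels
  p
}

#' Published baseline scale moments
#'
#' Scale-level means and standard deviations that the reference marginals
#' are calibrated against: effort 12.5 (1.9), reward 48.1 (3.2) and log
#' GHQ-12 Likert score 2.29 (0.20) in the unbiased (0% NA) condition.
#'
#' @param effort_mean,effort_sd Effort scale moments.
#' @param reward_mean,reward_sd Reward scale moments.
#' @param log_ghq_mean,log_ghq_sd Moments of the natural-log GHQ score.
#' @return A named list of the six targets.
#' @export
scale_targets <- function(effort_mean = 12.5, effort_sd = 1.9,
                          reward_mean = 48.1, reward_sd = 3.2,
                          log_ghq_mean = 2.29, log_ghq_sd = 0.20) {
  stopifnot(effort_sd > 0, reward_sd > 0, log_ghq_sd > 0,
            effort_mean > 6, effort_mean < 30,
            reward_mean > 11, reward_mean < 55)
  list(effort_mean = effort_mean, effort_sd = effort_sd,
       reward_mean = reward_mean, reward_sd = reward_sd,
       log_ghq_mean = log_ghq_mean, log_ghq_sd = log_ghq_sd)
}

#' @keywords internal
#' Raw-scale mean and SD implied by treating the log score as normal:
#' m = exp(mu + sigma^2/2), s = m * sqrt(exp(sigma^2) - 1).
lognormal_raw_moments <- function(log_mean, log_sd) {
  m <- exp(log_mean + log_sd^2 / 2)
  c(mean = m, sd = m * sqrt(expm1(log_sd^2)))
}

#' Build reference item marginals from published scale moments
#'
#' Constructs a 29-item marginal table whose implied scale-level moments
#' match `targets` under two assumptions: items within a scale are
#' exchangeable (identically distributed), and items are independent (so the
#' scale variance is the sum of item variances).  Each effort item is
#' calibrated to mean `effort_mean/6` and SD `sqrt(effort_sd^2/6)`, each
#' reward item analogously with 11 items, and each GHQ item to the raw-score
#' moments implied by a lognormal GHQ score with the stated log-scale
#' moments, split over 12 items.
#'
#' @param targets Scale moments, see [scale_targets()].
#' @param item_specs Item specification data frame.
#' @return A marginal table (long-format data frame).
#' @export
#' @examples
#' marg <- build_reference_marginals()
#' head(marg)
build_reference_marginals <- function(targets = scale_targets(),
                                      item_specs = default_item_specs()) {
  item_specs <- validate_item_specs(item_specs)
  ghq_raw <- lognormal_raw_moments(targets$log_ghq_mean, targets$log_ghq_sd)
  per_item <- list(
    ERI_EFFORT = calibrate_item_marginal(targets$effort_mean / 6,
                                         sqrt(targets$effort_sd^2 / 6), 1L, 5L),
    ERI_REWARD = calibrate_item_marginal(targets$reward_mean / 11,
                                         sqrt(targets$reward_sd^2 / 11), 1L, 5L),
    GHQ = calibrate_item_marginal(ghq_raw[["mean"]] / 12,
                                  sqrt(ghq_raw[["sd"]]^2 / 12), 0L, 3L)
  )
  out <- lapply(seq_len(nrow(item_specs)), function(i) {
    p <- per_item[[item_specs$instrument[i]]]
    data.frame(item_id = item_specs$item_id[i],
               level = as.integer(names(p)),
               probability = unname(p))
  })
  validate_marginal_table(do.call(rbind, out), item_specs)
}

#' Sample one null population of questionnaire responses
#'
#' Draws every cell of the subjects x items response matrix independently
#' from its item's marginal distribution, using R's global random number
#' stream.  Because columns are mutually independent by construction, any
#' observed exposure--outcome correlation in the sampled population is pure
#' sampling noise: this is the simulation's null model.
#'
#' Exactly `n_subjects * 29` uniforms are consumed, so the RNG state after
#' the call is a deterministic function of the state before it — the basis
#' of the shared-random-number coupling across bias conditions.
#'
#' @param marginals Marginal table (long format).
#' @param n_subjects Number of subjects (rows) to draw.
#' @param item_specs Item specification data frame; fixes the column order.
#' @return Integer matrix with `n_subjects` rows and one column per item,
#'   column names are the `item_id`s.
#' @export
sample_population <- function(marginals, n_subjects,
                              item_specs = default_item_specs()) {
  item_specs <- validate_item_specs(item_specs)
  marginals <- validate_marginal_table(marginals, item_specs)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  n_items <- nrow(item_specs)
  u <- matrix(stats::runif(n_subjects * n_items), n_subjects, n_items)
  out <- matrix(0L, n_subjects, n_items,
                dimnames = list(NULL, item_specs$item_id))
  for (i in seq_len(n_items)) {
    rows <- marginals[marginals$item_id == item_specs$item_id[i], ]
    rows <- rows[order(rows$level), ]
    cum <- cumsum(rows$probability)
    cum[length(cum)] <- 1  # guard against sum < 1 by rounding
    out[, i] <- as.integer(rows$level[findInterval(u[, i], cum) + 1L])
  }
  out
}

#' Read or write a marginal table CSV
#'
#' Long format with columns `item_id`, `level`, `probability`.
#'
#' @param path Path to a CSV file.
#' @param marginals Marginal table data frame.
#' @param item_specs Item specification used for validation.
#' @return `read_marginals()` returns a validated marginal table;
#'   `write_marginals()` returns `path` invisibly.
#' @export
read_marginals <- function(path, item_specs = default_item_specs()) {
  marg <- utils::read.csv(path, stringsAsFactors = FALSE)
  marg$level <- as.integer(marg$level)
  validate_marginal_table(marg, validate_item_specs(item_specs))
}

#' @rdname read_marginals
#' @export
write_marginals <- function(marginals, path,
                            item_specs = default_item_specs()) {
  validate_marginal_table(marginals, validate_item_specs(item_specs))
  utils::write.csv(marginals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
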