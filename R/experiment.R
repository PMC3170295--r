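#' Simulation run configuration
#'
#' Bundles everything a grid run needs.  Defaults reproduce the study
#' conditions: 10,000 populations of 300 subjects, NA prevalence grid
#' `{0, 5, 10, 20}%` by intensity grid `{0, 10, 20, 30, 40}%`, all three
#' regression models, reference marginals calibrated to the published
#' baselines.  For interactive work reduce `n_populations`; every
#' Monte-Carlo bound scales with `1/sqrt(n_populations)`.
#'
#' @param n_subjects Subjects per population (>= 10).
#' @param n_populations Populations per grid cell (>= 1).
#' @param p_grid NA prevalences (proportion of subjects with NA).
#' @param q_grid NA intensities (proportion of items affected).
#' @param models Subset of [model_ids()] to fit.
#' @param master_seed Integer master seed; every population's substream is
#'   derived from it and the population index.
#' @param log_offset Offset for [log_ghq()].
#' @param marginals_source `"reference"` or a path to a marginal-table CSV.
#' @param sd_method How Table-2-style score SDs are summarised:
#'   `"pooled"` (mean over populations of the within-population,
#'   between-subject SD — the scale-level SD) or `"across_populations"`
#'   (SD of the per-population means).
#' @return A list with class `"run_config"`.
#' @export
run_config <- function(n_subjects = 300L,
                       n_populations = 10000L,
                       p_grid = c(0, 0.05, 0.10, 0.20),
                       q_grid = c(0, 0.10, 0.20, 0.30, 0.40),
                       models = model_ids(),
                       master_seed = 1L,
                       log_offset = 0,
                       marginals_source = "reference",
                       sd_method = c("pooled", "across_populations")) {
  sd_method <- match.arg(sd_method)
  models <- match.arg(models, model_ids(), several.ok = TRUE)
  if (n_subjects < 10) stop("n_subjects must be >= 10", call. = FALSE)
  if (n_populations < 1) stop("n_populations must be >= 1", call. = FALSE)
  if (any(p_grid < 0 | p_grid > 1) || any(q_grid < 0 | q_grid > 1)) {
    stop("p_grid and q_grid must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_populations = as.integer(n_populations),
    p_grid = p_grid, q_grid = q_grid, models = models,
    master_seed = as.integer(master_seed),
    log_offset = log_offset,
    marginals_source = marginals_source,
    sd_method = sd_method
  ), class = "run_config")
}

#' Derive the seed of one population's random substream
#'
#' Deterministic 31-bit mix of the master seed and the population index, so
#' any population can be regenerated in isolation and grid cells can be
#' computed in any order.  The same index yields the same seed in every
#' grid cell — the shared-random-number coupling across bias conditions.
#'
#' @param master_seed Integer master seed.
#' @param population_index 1-based population index.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
population_seed <- function(master_seed, population_index) {
  m <- 2147483647  # 2^31 - 1; all products stay below 2^53
  x <- (as.numeric(master_seed) %% m + m) %% m
  x <- (x * 48271 + as.numeric(population_index) * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x %% (m - 1)) + 1L
}

#' Simulate, bias, score and fit one population
#'
#' Composes the full per-population pipeline: seed the substream from
#' `(master_seed, population_index)`, draw the null population, inject NA,
#' score all subjects, and fit the requested regression models.
#'
#' @param marginals Marginal table.
#' @param config A [run_config()].
#' @param na_config An [na_config()].
#' @param population_index 1-based population index.
#' @param item_specs Item specification data frame.
#' @return One-row data frame with the population index and seed, per-model
#'   R-squared and significance flags, and mean/SD of the four derived
#'   scores over subjects.
#' @export
run_population <- function(marginals, config, na_config, population_index,
                           item_specs = default_item_specs()) {
  set.seed(population_seed(config$master_seed, population_index))
  pop <- sample_population(marginals, config$n_subjects, item_specs)
  pop <- inject_na(pop, na_config, item_specs)
  scored <- score_population(pop, item_specs, log_offset = config$log_offset)

  rec <- data.frame(
    population_index = population_index,
    p_subject = na_config$p_subject,
    q_items = na_config$q_items,
    mean_log_ghq = mean(scored$log_ghq),
    sd_log_ghq = stats::sd(scored$log_ghq),
    mean_effort = mean(scored$effort),
    sd_effort = stats::sd(scored$effort),
    mean_reward = mean(scored$reward),
    sd_reward = stats::sd(scored$reward),
    mean_eri_ratio = mean(scored$eri_ratio),
    sd_eri_ratio = stats::sd(scored$eri_ratio),
    degenerate = FALSE
  )
  for (model in config$models) {
    d <- build_design(scored, model)
    fit <- fit_linear_model(d$y, d$X, model)
    pre <- model_prefix(model)
    rec[[paste0(pre, "_r2")]] <- fit$r_squared
    if (model == "EFFORT_REWARD") {
      rec$er_sig_effort <- fit$coefficients$significant[1]
      rec$er_sig_reward <- fit$coefficients$significant[2]
      rec$er_sig_both <- fit$both_significant
    } else {
      rec[[paste0(pre, "_sig")]] <- fit$coefficients$significant[1]
    }
    rec$degenerate <- rec$degenerate || fit$degenerate
  }
  rec
}

#' @keywords internal
model_prefix <- function(model_id) {
  c(LOG_RATIO = "log_ratio", RATIO = "ratio", EFFORT_REWARD = "er")[[model_id]]
}

#' Run all populations of one grid cell and summarise
#'
#' Aggregates `n_populations` per-population records into the cell summary:
#' mean R-squared (reported as a percentage), the fraction of populations in
#' which each coefficient is significant at the 5% level, and mean/SD
#' summaries of the four derived scores.  Populations with a degenerate
#' (rank-deficient) fit are excluded from the aggregates and counted in
#' `n_excluded`.
#'
#' @inheritParams run_population
#' @param .records If `TRUE`, attach the per-population records as the
#'   `"records"` attribute of the summary row.
#' @return One-row data frame (a grid-cell summary).
#' @export
run_cell <- function(marginals, config, na_config,
                     item_specs = default_item_specs(), .records = FALSE) {
  recs <- vector("list", config$n_populations)
  for (i in seq_len(config$n_populations)) {
    recs[[i]] <- run_population(marginals, config, na_config, i, item_specs)
  }
  recs <- do.call(rbind, recs)
  out <- summarise_records(recs, config)
  if (.records) attr(out, "records") <- recs
  out
}

#' @keywords internal
summarise_records <- function(recs, config) {
  keep <- !recs$degenerate
  ok <- recs[keep, , drop = FALSE]
  if (nrow(ok) == 0) stop("all populations in the cell were degenerate",
                          call. = FALSE)
  out <- data.frame(
    p_subject = recs$p_subject[1],
    q_items = recs$q_items[1],
    n_populations = nrow(recs),
    n_excluded = sum(!keep)
  )
  for (model in config$models) {
    pre <- model_prefix(model)
    out[[paste0(pre, "_mean_r2_pct")]] <- 100 * mean(ok[[paste0(pre, "_r2")]])
    if (model == "EFFORT_REWARD") {
      out$er_prop_sig_effort <- mean(ok$er_sig_effort)
      out$er_prop_sig_reward <- mean(ok$er_sig_reward)
      out$er_prop_sig_both <- mean(ok$er_sig_both)
    } else {
      out[[paste0(pre, "_prop_sig")]] <- mean(ok[[paste0(pre, "_sig")]])
    }
  }
  for (score in c("log_ghq", "effort", "reward", "eri_ratio")) {
    out[[paste0("mean_", score)]] <- mean(ok[[paste0("mean_", score)]])
    out[[paste0("sd_", score)]] <-
      if (config$sd_method == "pooled") mean(ok[[paste0("sd_", score)]])
      else stats::sd(ok[[paste0("mean_", score)]])
  }
  out
}

#' Run the full bias grid
#'
#' One [run_cell()] per `(p_subject, q_items)` combination of the config's
#' grids.  Cells share the per-population substreams (shared random
#' numbers), so summaries are directly comparable across conditions and the
#' result is independent of cell order.  A failed cell is reported as a row
#' with an `error` message rather than silently dropped.
#'
#' @param config A [run_config()].
#' @param item_specs Item specification data frame.
#' @param marginals Optional marginal table overriding
#'   `config$marginals_source`.
#' @param progress If `TRUE`, log per-cell progress to stderr.
#' @return Data frame with one grid-cell summary per row.
#' @export
run_grid <- function(config = run_config(),
                     item_specs = default_item_specs(),
                     marginals = NULL, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(marginals)) {
    marginals <- if (identical(config$marginals_source, "reference")) {
      build_reference_marginals(item_specs = item_specs)
    } else {
      read_marginals(config$marginals_source, item_specs)
    }
  }
  cells <- expand.grid(p_subject = config$p_grid, q_items = config$q_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (progress) {
      message(sprintf("cell %d/%d: p = %.2f, q = %.2f",
                      i, nrow(cells), cells$p_subject[i], cells$q_items[i]))
    }
    rows[[i]] <- tryCatch({
      s <- run_cell(marginals, config,
                    na_config(cells$p_subject[i], cells$q_items[i]),
                    item_specs)
      s$error <- NA_character_
      s
    }, error = function(e) {
      data.frame(p_subject = cells$p_subject[i], q_items = cells$q_items[i],
                 n_populations = NA_integer_, n_excluded = NA_integer_,
                 error = conditionMessage(e))
    })
  }
  merge_rows(rows)
}

#' @keywords internal
merge_rows <- function(rows) {
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  do.call(rbind, rows)
}
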