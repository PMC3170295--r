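#' Interpret an observed explained variance against the simulated grid
#'
#' Applies the interpretation bands for an observed ERI--GHQ explained
#' variance: 5% and below, treat with caution (NA alone can plausibly
#' produce it); between 5% and 10%, possibly NA but unlikely; 10% and
#' above, not likely the result of NA.  In addition, the minimal bias
#' conditions able to account for the observation are located on the grid:
#' for each model, the Pareto-minimal `(p_subject, q_items)` cells whose
#' simulated mean R-squared reaches the observed value.
#'
#' @param observed_r2_percent Observed explained variance, in percent.
#' @param grid Grid summary data frame from [run_grid()].
#' @return A list with `observed_r2_percent`, `band` (one of `"caution"`,
#'   `"possibly_na_unlikely"`, `"not_likely_na"`) and `minimal_cells`, a
#'   data frame of Pareto-minimal reaching cells per model (zero rows when
#'   no simulated cell reaches the observation).
#' @export
#' @examples
#' \dontrun{
#' grid <- run_grid(run_config(n_populations = 200))
#' interpret_r2(6, grid)
#' }
interpret_r2 <- function(observed_r2_percent, grid) {
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    stop("grid must be a non-empty grid summary", call. = FALSE)
  }
  if (observed_r2_percent < 0 || observed_r2_percent > 100) {
    stop("observed_r2_percent must be in [0, 100]", call. = FALSE)
  }
  band <- if (observed_r2_percent <= 5) "caution"
          else if (observed_r2_percent < 10) "possibly_na_unlikely"
          else "not_likely_na"

  r2_cols <- grep("_mean_r2_pct$", names(grid), value = TRUE)
  minimal <- list()
  for (col in r2_cols) {
    model <- names(which(vapply(model_ids(), function(m) {
      paste0(model_prefix(m), "_mean_r2_pct") == col
    }, logical(1))))
    reach <- grid[!is.na(grid[[col]]) & grid[[col]] >= observed_r2_percent, ,
                  drop = FALSE]
    if (nrow(reach) == 0) next
    keep <- vapply(seq_len(nrow(reach)), function(i) {
      !any(reach$p_subject <= reach$p_subject[i] &
             reach$q_items <= reach$q_items[i] &
             (reach$p_subject < reach$p_subject[i] |
                reach$q_items < reach$q_items[i]))
    }, logical(1))
    cells <- reach[keep, c("p_subject", "q_items", col)]
    names(cells)[3] <- "mean_r2_pct"
    cells$model_id <- model
    minimal[[col]] <- cells
  }
  minimal_cells <- if (length(minimal)) do.call(rbind, minimal) else
    data.frame(p_subject = numeric(0), q_items = numeric(0),
               mean_r2_pct = numeric(0), model_id = character(0))
  rownames(minimal_cells) <- NULL
  list(observed_r2_percent = observed_r2_percent, band = band,
       minimal_cells = minimal_cells)
}

#' Write grid summaries in the printed-table layouts
#'
#' Writes four files to `out_dir`:
#' \describe{
#'   \item{`table1.csv`}{Per model and NA prevalence (rows), mean R-squared
#'     in percent and proportion of significant coefficients per NA
#'     intensity (columns), rounded to 2 decimals.  The two-predictor model
#'     reports the effort / reward / both-significant proportions.}
#'   \item{`table2.csv`}{Mean (SD) of the log GHQ score, effort score,
#'     reward score and ERI ratio per cell.}
#'   \item{`results_long.csv`}{The full-precision grid summary, one row per
#'     cell.}
#'   \item{`manifest.json`}{Run configuration, master seed and package
#'     version, for reproducibility.}
#' }
#'
#' @param summaries Grid summary data frame from [run_grid()].
#' @param out_dir Output directory, created if needed.
#' @param config The [run_config()] of the run (stored in the manifest).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(summaries, out_dir, config = NULL) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0) {
    stop("summaries must be a non-empty grid summary", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- summaries[order(summaries$p_subject, summaries$q_items), ]
  qs <- sort(unique(s$q_items))
  ps <- sort(unique(s$p_subject))

  fmt_q <- function(q) sprintf("q%02.0f", 100 * q)
  t1 <- list()
  for (model in model_ids()) {
    pre <- model_prefix(model)
    r2col <- paste0(pre, "_mean_r2_pct")
    if (!r2col %in% names(s)) next
    for (p in ps) {
      row <- data.frame(model_id = model, p_subject = p)
      for (q in qs) {
        cell <- s[s$p_subject == p & s$q_items == q, ]
        r2 <- if (nrow(cell)) round(cell[[r2col]], 2) else NA_real_
        sig <- if (nrow(cell) == 0) NA_character_
          else if (model == "EFFORT_REWARD") {
            sprintf("%.2f/%.2f/%.2f", cell$er_prop_sig_effort,
                    cell$er_prop_sig_reward, cell$er_prop_sig_both)
          } else sprintf("%.2f", cell[[paste0(pre, "_prop_sig")]])
        row[[paste0(fmt_q(q), "_r2_pct")]] <- r2
        row[[paste0(fmt_q(q), "_prop_sig")]] <- sig
      }
      t1[[length(t1) + 1]] <- row
    }
  }
  t1 <- merge_rows(t1)

  t2 <- list()
  for (score in c("log_ghq", "effort", "reward", "eri_ratio")) {
    digits <- if (score %in% c("log_ghq", "eri_ratio")) "%.3f(%.3f)" else "%.1f(%.1f)"
    for (p in ps) {
      row <- data.frame(score = score, p_subject = p)
      for (q in qs) {
        cell <- s[s$p_subject == p & s$q_items == q, ]
        row[[fmt_q(q)]] <- if (nrow(cell))
          sprintf(digits, cell[[paste0("mean_", score)]],
                  cell[[paste0("sd_", score)]]) else NA_character_
      }
      t2[[length(t2) + 1]] <- row
    }
  }
  t2 <- merge_rows(t2)

  paths <- file.path(out_dir,
                     c("table1.csv", "table2.csv", "results_long.csv",
                       "manifest.json"))
  utils::write.csv(t1, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(t2, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(s, paths[3], row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "nabiassim",
    version = as.character(utils::packageVersion("nabiassim")),
    config = if (is.null(config)) NULL else unclass(config)
  )
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
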