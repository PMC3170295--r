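test_that("population substream seeds are deterministic 31-bit integers", {
  s1 <- population_seed(123L, 1)
  expect_identical(s1, population_seed(123L, 1))
  expect_true(s1 >= 1 && s1 < 2^31)
  many <- vapply(1:500, population_seed, integer(1), master_seed = 123L)
  expect_false(any(duplicated(many)))
  expect_false(population_seed(123L, 1) == population_seed(124L, 1))
})

test_that("one population's record is reproducible and bias-coupled", {
  marg <- build_reference_marginals()
  cfg <- run_config(n_subjects = 100, n_populations = 1, master_seed = 55)

  base <- run_population(marg, cfg, na_config(0, 0), 3)
  expect_identical(base, run_population(marg, cfg, na_config(0, 0), 3))
  expect_true(base$log_ratio_r2 >= 0 && base$log_ratio_r2 <= 1)
  expect_true(base$er_r2 >= 0 && base$er_r2 <= 1)

  biased <- run_population(marg, cfg, na_config(0.2, 0.4), 3)
  expect_gte(biased$mean_eri_ratio, base$mean_eri_ratio)
  expect_gte(biased$mean_log_ghq, base$mean_log_ghq)
  expect_lte(biased$mean_reward, base$mean_reward)
})

test_that("a single-population cell summary equals its record", {
  marg <- build_reference_marginals()
  cfg <- run_config(n_subjects = 80, n_populations = 1, master_seed = 9)
  cell <- run_cell(marg, cfg, na_config(0.1, 0.2), .records = TRUE)
  rec <- attr(cell, "records")
  expect_equal(nrow(rec), 1)
  expect_equal(cell$log_ratio_mean_r2_pct, 100 * rec$log_ratio_r2)
  expect_equal(cell$er_prop_sig_both, as.numeric(rec$er_sig_both))
  expect_equal(cell$mean_effort, rec$mean_effort)
  expect_equal(cell$n_excluded, 0)
})

test_that("the grid covers the full product and baselines coincide", {
  cfg <- run_config(n_subjects = 60, n_populations = 2,
                    p_grid = c(0, 0.1, 0.5), q_grid = c(0, 0.3),
                    master_seed = 7)
  grid <- run_grid(cfg)
  expect_equal(nrow(grid), 6)
  expect_true(all(is.na(grid$error)))

  # with q = 0 the injection is the identity, so every (p, 0) cell is
  # bit-identical to the (0, 0) baseline under shared substreams
  base <- grid[grid$p_subject == 0 & grid$q_items == 0, ]
  for (p in c(0.1, 0.5)) {
    cell <- grid[grid$p_subject == p & grid$q_items == 0, ]
    cols <- setdiff(names(grid), c("p_subject", "q_items"))
    expect_equal(cell[cols], base[cols], ignore_attr = TRUE)
  }
})

test_that("tables are written in the printed layouts and reproducibly", {
  cfg <- run_config(n_subjects = 60, n_populations = 2,
                    p_grid = c(0, 0.2), q_grid = c(0, 0.4), master_seed = 3)
  grid <- run_grid(cfg)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  paths <- write_tables(grid, out1, cfg)
  expect_true(all(file.exists(paths)))

  t1 <- utils::read.csv(file.path(out1, "table1.csv"), check.names = FALSE)
  expect_equal(nrow(t1), 3 * 2)  # three models x two prevalences
  expect_true(all(c("q00_r2_pct", "q00_prop_sig", "q40_r2_pct") %in% names(t1)))
  # the two-predictor rows carry the e/r/both triple
  er <- t1[t1$model_id == "EFFORT_REWARD", "q40_prop_sig"]
  expect_true(all(grepl("^\\d\\.\\d{2}/\\d\\.\\d{2}/\\d\\.\\d{2}$", er)))

  t2 <- utils::read.csv(file.path(out1, "table2.csv"), check.names = FALSE)
  expect_equal(nrow(t2), 4 * 2)  # four scores x two prevalences
  expect_true(all(grepl("\\(", t2$q00)))

  # byte-identical long-format output on re-run
  write_tables(grid, out2, cfg)
  expect_identical(readLines(file.path(out1, "results_long.csv")),
                   readLines(file.path(out2, "results_long.csv")))

  expect_error(write_tables(grid[0, ], out1), "non-empty")
})

test_that("explained-variance interpretation applies the bands and finds minimal cells", {
  grid <- data.frame(
    p_subject = rep(c(0.05, 0.10, 0.20), each = 2),
    q_items = rep(c(0.30, 0.40), 3),
    log_ratio_mean_r2_pct = c(1.0, 2.0, 2.3, 5.1, 5.3, 11.3)
  )
  expect_equal(interpret_r2(3, grid)$band, "caution")
  expect_equal(interpret_r2(5, grid)$band, "caution")
  expect_equal(interpret_r2(6, grid)$band, "possibly_na_unlikely")
  expect_equal(interpret_r2(12, grid)$band, "not_likely_na")

  # cells reaching 5%: (0.10, 0.40), (0.20, 0.30), (0.20, 0.40); the last
  # is dominated, the first two are Pareto-minimal
  res <- interpret_r2(5, grid)
  cells <- res$minimal_cells[order(res$minimal_cells$p_subject), ]
  expect_equal(cells$p_subject, c(0.10, 0.20))
  expect_equal(cells$q_items, c(0.40, 0.30))

  res_none <- interpret_r2(50, grid)
  expect_equal(nrow(res_none$minimal_cells), 0)
  expect_error(interpret_r2(3, grid[0, ]), "non-empty")
})

test_that("the command-line interface drives calibrate, run and interpret", {
  tmp <- withr::local_tempdir()
  marg_csv <- file.path(tmp, "marg.csv")
  expect_equal(suppressMessages(cli_main(c("calibrate", "--out", marg_csv))), 0L)
  expect_equal(read_marginals(marg_csv)$probability,
               build_reference_marginals()$probability, tolerance = 1e-12)

  out_dir <- file.path(tmp, "res")
  status <- suppressMessages(cli_main(c(
    "run", "--n-subjects", "60", "--n-populations", "2",
    "--p-grid", "0,0.2", "--q-grid", "0,0.4", "--seed", "5",
    "--marginals", marg_csv, "--out-dir", out_dir)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out_dir, "results_long.csv")))

  out <- capture.output(
    status <- cli_main(c("interpret", "--r2", "6", "--grid",
                         file.path(out_dir, "results_long.csv"))))
  expect_equal(status, 0L)
  expect_true(any(grepl("possibly_na_unlikely", out)))

  expect_equal(suppressMessages(cli_main(c("bogus"))), 1L)
  expect_error(cli_main(c("run", "--n-subjects")), "needs a value")
})
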