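test_that("empirical marginals are relative frequencies on the full support", {
  specs <- default_item_specs()
  set.seed(3)
  pop <- random_population(4)
  pop[, "effort_1"] <- c(1L, 1L, 2L, 1L)
  pop[, "esteem_2"] <- 3L
  marg <- estimate_marginals(pop, specs)

  e1 <- marg[marg$item_id == "effort_1", ]
  expect_equal(e1$probability[order(e1$level)], c(3, 1, 0, 0, 0) / 4)
  s2 <- marg[marg$item_id == "esteem_2", ]
  expect_equal(s2$probability[order(s2$level)], c(0, 0, 1, 0, 0))
  sums <- tapply(marg$probability, marg$item_id, sum)
  expect_equal(as.vector(sums), rep(1, 29))
})

test_that("item calibration matches target moments across regimes", {
  # near-degenerate limit: vanishing SD at an integer mean is a point mass
  p <- calibrate_item_marginal(3, 1e-9, 1, 5)
  expect_equal(unname(p), c(0, 0, 1, 0, 0))

  cases <- list(
    symmetric_wide = list(mean = 3, sd = sqrt(2), lo = 1, hi = 5),
    effort_item = list(mean = 12.5 / 6, sd = sqrt(1.9^2 / 6), lo = 1, hi = 5),
    reward_item = list(mean = 48.1 / 11, sd = sqrt(3.2^2 / 11), lo = 1, hi = 5),
    ghq_item = list(mean = 10.07 / 12, sd = 2.03 / sqrt(12), lo = 0, hi = 3)
  )
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    p <- calibrate_item_marginal(cs$mean, cs$sd, cs$lo, cs$hi)
    expect_true(all(p >= 0), info = nm)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    mom <- marginal_moments(p)
    expect_equal(mom[["mean"]], cs$mean, tolerance = 1e-4, info = nm)
    expect_equal(mom[["sd"]], cs$sd, tolerance = 1e-4, info = nm)
  }
  # symmetric case: mean within the tighter stated tolerance and symmetric
  p <- calibrate_item_marginal(3, sqrt(2), 1, 5)
  expect_equal(marginal_moments(p)[["mean"]], 3, tolerance = 1e-6)
  expect_equal(unname(p), unname(rev(p)), tolerance = 1e-6)

  # calibration is deterministic
  expect_identical(calibrate_item_marginal(2.0833, 0.7757, 1, 5),
                   calibrate_item_marginal(2.0833, 0.7757, 1, 5))
})

test_that("infeasible moment targets raise calibration errors naming the bound", {
  expect_error(calibrate_item_marginal(4.5, 2.0, 1, 5), "exceeds the maximum")
  expect_error(calibrate_item_marginal(2.5, 0.1, 1, 5), "below the minimum")
  expect_error(calibrate_item_marginal(0.5, 0.5, 1, 5), "strictly inside")
  expect_error(calibrate_item_marginal(2.7, 1e-9, 1, 5), "integer target_mean")
})

test_that("reference marginals reproduce the published scale baselines", {
  marg <- build_reference_marginals()
  specs <- default_item_specs()
  set.seed(101)
  # one large population: n = 1e5 subject draws (>= the 1e5-draw design)
  pop <- sample_population(marg, 1e5, specs)
  scored <- score_population(pop, specs, log_offset = 1)

  # effort mean within 2 Monte-Carlo SEs of 12.5
  se_eff <- 1.9 / sqrt(1e5)
  expect_lt(abs(mean(scored$effort) - 12.5), 2 * se_eff)
  # reward mean and SD
  expect_lt(abs(mean(scored$reward) - 48.1), 2 * 3.2 / sqrt(1e5))
  expect_lt(abs(stats::sd(scored$reward) - 3.2), 0.05)
  expect_lt(abs(stats::sd(scored$effort) - 1.9), 0.05)
  # GHQ raw-score mean ~ exp(2.29 + 0.02) = 10.07 under the lognormal
  # back-transformation
  expect_lt(abs(mean(scored$ghq) - exp(2.29 + 0.02)), 0.05)
})

test_that("null sampling honours marginals, independence and the seed contract", {
  specs <- default_item_specs()
  marg <- build_reference_marginals()

  # point-mass marginals give a constant matrix
  pm <- marg
  for (id in unique(pm$item_id)) {
    rows <- pm$item_id == id
    lev <- pm$level[rows]
    pm$probability[rows] <- as.numeric(lev == max(lev) - 1L)
  }
  set.seed(5)
  pop <- sample_population(pm, 10, specs)
  expect_true(all(pop[, "effort_1"] == 4L))
  expect_true(all(pop[, "ghq_1"] == 2L))
  expect_equal(length(unique(as.vector(pop[, specs$instrument != "GHQ"]))), 1)

  # a half-half item marginal: observed frequency within 3 binomial SEs
  half <- marg  # rows per item are in level order by construction
  half$probability[half$item_id == "effort_1"] <- c(0.5, 0.5, 0, 0, 0)
  set.seed(6)
  pop <- sample_population(half, 1e5, specs)
  f1 <- mean(pop[, "effort_1"] == 1L)
  expect_lt(abs(f1 - 0.5), 3 * sqrt(0.25 / 1e5))

  # columns are independent: sample correlation within 3/sqrt(n) of 0
  expect_lt(abs(stats::cor(pop[, "effort_2"], pop[, "ghq_3"])), 3 / sqrt(1e5))

  # seed contract: identical (marginals, n, seed) -> bit-identical draws
  set.seed(42); a <- sample_population(marg, 50, specs)
  set.seed(42); b <- sample_population(marg, 50, specs)
  expect_identical(a, b)

  expect_error(sample_population(marg, 0, specs), "n_subjects")
})

test_that("estimate/sample round trip recovers the marginal table", {
  specs <- default_item_specs()
  marg <- build_reference_marginals()
  set.seed(8)
  pop <- sample_population(marg, 2e4, specs)
  est <- estimate_marginals(pop, specs)
  for (id in c("effort_1", "esteem_3", "ghq_5")) {
    truth <- marg[marg$item_id == id, ]
    got <- est[est$item_id == id, ]
    truth <- truth[order(truth$level), ]
    got <- got[order(got$level), ]
    # multinomial sampling error: 4 SEs per level probability
    tol <- 4 * sqrt(pmax(truth$probability * (1 - truth$probability), 1e-6) / 2e4)
    expect_true(all(abs(got$probability - truth$probability) < tol), info = id)
  }
})

test_that("marginal tables survive CSV round trips and reject bad tables", {
  marg <- build_reference_marginals()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_marginals(marg, tmp)
  back <- read_marginals(tmp)
  expect_equal(back$probability, marg$probability, tolerance = 1e-12)

  bad <- marg
  bad$probability[1] <- bad$probability[1] + 0.1
  expect_error(write_marginals(bad, tmp), "sum to 1")
  expect_error(
    validate_marginal_table(marg[marg$item_id != "ghq_1", ],
                            default_item_specs()),
    "cover all items")
})
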