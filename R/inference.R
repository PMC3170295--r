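#' Model identifiers
#'
#' The three regressions fitted to every simulated population, each with the
#' log GHQ-12 Likert score as dependent variable: `LOG_RATIO` (single
#' predictor, log-transformed ERI ratio), `RATIO` (single predictor,
#' untransformed ERI ratio) and `EFFORT_REWARD` (effort and reward scores as
#' two independent variables).
#'
#' @return Character vector of the three model ids.
#' @export
model_ids <- function() c("LOG_RATIO", "RATIO", "EFFORT_REWARD")

#' Build the design of one regression model
#'
#' @param scored Scored population as returned by [score_population()].
#' @param model_id One of [model_ids()].
#' @return A list with `y` (log GHQ score vector) and `X` (numeric matrix
#'   with one or two named predictor columns).
#' @export
build_design <- function(scored, model_id = model_ids()) {
  model_id <- match.arg(model_id)
  if (!is.data.frame(scored) || nrow(scored) == 0) {
    stop("scored must be a non-empty scored population", call. = FALSE)
  }
  X <- switch(model_id,
    LOG_RATIO = cbind(log_eri_ratio = scored$log_eri_ratio),
    RATIO = cbind(eri_ratio = scored$eri_ratio),
    EFFORT_REWARD = cbind(effort = scored$effort, reward = scored$reward)
  )
  list(y = scored$log_ghq, X = X)
}

#' Fit one ordinary least squares model and extract the stored statistics
#'
#' OLS with intercept; coefficient p-values are two-sided t tests on
#' `n - k - 1` degrees of freedom and `r_squared` is the unadjusted
#' coefficient of determination.  Significance is strict: `p < 0.05`.
#'
#' A rank-deficient design with more than the intercept's worth of
#' redundancy (e.g. a zero-variance predictor) does not raise: the result is
#' flagged `degenerate` with `NA` statistics, so a long grid run can exclude
#' rather than die on a pathological population.
#'
#' @param y Numeric response vector.
#' @param X Numeric predictor matrix (1 or 2 named columns).
#' @param model_id One of [model_ids()].
#' @return A list with class `"regression_result"`: `model_id`,
#'   `r_squared`, `coefficients` (data frame with `term`, `estimate`,
#'   `p_value`, `significant`), `both_significant` (only for
#'   `EFFORT_REWARD`), `degenerate`.
#' @export
fit_linear_model <- function(y, X, model_id = model_ids()) {
  model_id <- match.arg(model_id)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  k <- ncol(X)
  if (length(y) < k + 2) {
    stop("need at least k + 2 observations", call. = FALSE)
  }

  dat <- data.frame(.y = y, X)
  terms <- setdiff(names(dat), ".y")
  fit <- stats::lm(.y ~ ., data = dat)
  fit_summary <- summary(fit)
  coefs <- fit_summary$coefficients
  r2 <- fit_summary$r.squared

  if (anyNA(stats::coef(fit)) || !all(terms %in% rownames(coefs))) {
    res <- list(
      model_id = model_id, r_squared = NA_real_,
      coefficients = data.frame(term = terms, estimate = NA_real_,
                                p_value = NA_real_, significant = NA),
      degenerate = TRUE
    )
    if (model_id == "EFFORT_REWARD") res$both_significant <- NA
    class(res) <- "regression_result"
    return(res)
  }

  ct <- coefs[terms, , drop = FALSE]
  coef_df <- data.frame(
    term = terms,
    estimate = unname(ct[, "Estimate"]),
    p_value = unname(ct[, "Pr(>|t|)"]),
    significant = unname(ct[, "Pr(>|t|)"] < 0.05)
  )
  res <- list(model_id = model_id, r_squared = r2,
              coefficients = coef_df, degenerate = FALSE)
  if (model_id == "EFFORT_REWARD") {
    res$both_significant <- all(coef_df$significant)
  }
  class(res) <- "regression_result"
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS model %s: R^2 = %s\n", x$model_id,
              format(x$r_squared, digits = 4)))
  print(x$coefficients, row.names = FALSE)
  if (!is.null(x$both_significant)) {
    cat("both coefficients significant:", x$both_significant, "\n")
  }
  invisible(x)
}
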