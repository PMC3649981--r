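# Aggregate statistics over classified duplicate pairs: group rates, 2x2
# association tests, equal-size-bin divergence curves, logistic trends on
# unbinned data, and the expression-controlled evolutionary-rate model.

#' Round a percentage half-up to one decimal
#'
#' Presentation rounding used in reports (`6.29% -> 6.3%`); computations
#' always use the exact ratio, never the rounded value.
#'
#' @param percent Numeric percentage.
#' @return Numeric, rounded half-up to one decimal place.
#' @export
percent_round <- function(percent) {
  sign(percent) * floor(abs(percent) * 10 + 0.5) / 10
}

#' A rate record
#'
#' @param numerator Non-negative integer count.
#' @param denominator Positive integer count.
#' @param group Optional group label.
#' @return List with `group`, `numerator`, `denominator`, `rate` (exact
#'   ratio) and `percent` (half-up presentation rounding to one decimal).
#' @export
rate <- function(numerator, denominator, group = NA_character_) {
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  r <- numerator / denominator
  list(group = group, numerator = numerator, denominator = denominator,
       rate = r, percent = percent_round(100 * r))
}

#' Two-by-two association test
#'
#' Runs a chi-squared test (with or without Yates continuity correction) or
#' Fisher's exact test on a 2x2 count table. A warning is raised when any
#' expected count is below 5 and an asymptotic method was requested.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param method `"chi2_yates"` (default), `"chi2"` or `"fisher"`.
#' @return List with `statistic` (`NA` for Fisher), `p_value`, `method`,
#'   `expected_warning`.
#' @export
contingency_test <- function(table,
                             method = c("chi2_yates", "chi2", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate margins in the 2x2 table", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  low <- any(expected < 5)
  if (method == "fisher") {
    ht <- stats::fisher.test(table)
    return(list(statistic = NA_real_, p_value = ht$p.value,
                method = method, expected_warning = FALSE))
  }
  if (low) {
    warning("expected count below 5; consider method = \"fisher\"",
            call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::chisq.test(table, correct = method == "chi2_yates"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method, expected_warning = low)
}

#' Equal-size-bin rate curve
#'
#' Sorts the data by the predictor (stable order, so boundary ties resolve
#' deterministically), splits it into `n_bins` contiguous bins whose sizes
#' differ by at most one (any remainder goes to the lowest-x bins), and
#' summarises each bin as the median predictor value and the outcome rate.
#'
#' @param x Numeric predictor (e.g. pairwise Ka).
#' @param y Logical outcome per observation.
#' @param n_bins Number of bins; must not exceed `length(x)`.
#' @return Data frame with `x_median`, `rate`, `n` per bin.
#' @export
binned_rate_curve <- function(x, y, n_bins) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n_bins > n) stop("n_bins exceeds the number of observations",
                       call. = FALSE)
  ord <- order(x)  # stable in R
  x <- x[ord]
  y <- as.logical(y[ord])
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  idx <- rep(seq_len(n_bins), times = sizes)
  data.frame(
    x_median = as.numeric(tapply(x, idx, stats::median)),
    rate = as.numeric(tapply(y, idx, mean)),
    n = as.integer(sizes),
    row.names = NULL)
}

#' Logistic trend on unbinned data
#'
#' Maximum-likelihood logistic regression of a binary outcome on a numeric
#' predictor, reporting the slope and its Wald p-value. Complete or
#' quasi-complete separation is flagged and the p-value set to `NA`.
#'
#' @param x Numeric predictor.
#' @param y Logical (or 0/1) outcome.
#' @return List with `slope`, `p_value`, `separation`.
#' @export
logistic_trend <- function(x, y) {
  y <- as.integer(as.logical(y))
  if (length(unique(x)) < 2) {
    stop("need at least two distinct predictor values", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("outcome is constant; no trend can be fit", call. = FALSE)
  }
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  separation <- sep_warned || abs(co["x", "Estimate"]) > 1e3
  list(slope = unname(co["x", "Estimate"]),
       p_value = if (separation) NA_real_ else unname(co["x", "Pr(>|z|)"]),
       separation = separation)
}

#' Expression-controlled evolutionary-rate model
#'
#' Linear model of `log(dN + 1)` on `log2(expression)` plus a binary class
#' flag (e.g. essential versus non-essential), with an interaction pretest:
#' the class comparison is only valid (an analysis of covariance can be
#' performed) when the expression-by-class interaction is not significant.
#'
#' @param dN Non-negative evolutionary rates.
#' @param expression Positive expression levels.
#' @param class_flag Logical class indicator.
#' @param interaction_alpha Significance level of the interaction pretest.
#' @return List with `coefficients` (data frame: term, estimate, p_value),
#'   `interaction_p`, `ancova_valid`.
#' @export
expression_controlled_rate_model <- function(dN, expression, class_flag,
                                             interaction_alpha = 0.05) {
  stopifnot(all(dN >= 0), all(expression > 0))
  flag <- as.logical(class_flag)
  if (length(unique(flag)) < 2) {
    stop("class_flag must contain both classes", call. = FALSE)
  }
  resp <- log(dN + 1)
  ex <- log2(expression)
  full <- stats::lm(resp ~ ex * flag)
  if (any(is.na(stats::coef(full)))) {
    stop("rank-deficient model; predictors are confounded", call. = FALSE)
  }
  inter_p <- summary(full)$coefficients["ex:flagTRUE", "Pr(>|t|)"]
  add <- stats::lm(resp ~ ex + flag)
  co <- summary(add)$coefficients
  coef_tab <- data.frame(
    term = c("intercept", "log2_expression", "class_flag"),
    estimate = unname(co[, "Estimate"]),
    p_value = unname(co[, "Pr(>|t|)"]),
    stringsAsFactors = FALSE)
  list(coefficients = coef_tab,
       interaction_p = unname(inter_p),
       # NaN arises on exact fits (zero residual variance): no evidence of
       # interaction, but no test either
       ancova_valid = if (is.nan(inter_p)) NA else
         inter_p >= interaction_alpha)
}
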