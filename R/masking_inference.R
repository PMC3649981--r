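# The phenotype-masking statistic: control-normalised fitness, the
# multiplicative expectation for a double knockdown, a one-sided rank test
# against that expectation, the qualitative escalation rule, and the
# none/partial/full masking classification.

#' Control-normalised fitness
#'
#' Each replicate measure is divided by the mean of the control wells, so a
#' value of 1 means indistinguishable from controls and values below 1 mean
#' reduced fitness. Measures must be oriented so that larger = healthier
#' (brood size, viability fractions, fraction morphologically normal);
#' normalised values may exceed 1.
#'
#' @param observed Numeric vector of replicate measures for one condition.
#' @param controls Numeric vector of the same measure over control wells.
#' @return Numeric vector of fitness values `w`, one per replicate.
#' @export
normalize_fitness <- function(observed, controls) {
  if (length(controls) == 0 || !all(is.finite(controls))) {
    stop("controls must be a non-empty finite vector", call. = FALSE)
  }
  m <- mean(controls)
  if (m <= 0) {
    stop("normalization error: control mean is not positive", call. = FALSE)
  }
  observed / m
}

#' Multiplicative expectation for a double knockdown
#'
#' Under a multiplicative model of interaction, if the single-knockdown
#' fitnesses are `w1 = 1 - s1` and `w2 = 1 - s2`, the expected
#' double-knockdown fitness is `(1 - s1)(1 - s2) = w1 * w2`.
#'
#' @param w1,w2 Single-knockdown fitness values (vectors recycle as usual).
#' @return `w1 * w2`.
#' @export
expected_double <- function(w1, w2) {
  stopifnot(all(w1 >= 0), all(w2 >= 0))
  w1 * w2
}

#' One-sided rank test for quantitative masking
#'
#' Tests whether the observed double-knockdown fitness replicates are
#' stochastically smaller than the multiplicative expectation formed from
#' the single-knockdown replicates, with a one-sided Mann-Whitney U test.
#' The expected sample is built either by pairing replicates
#' (`w1[i] * w2[i]`, the default: the products are mutually independent, so
#' the rank test's independence assumption holds) or from all cross-products
#' `w1[i] * w2[j]` (uses every combination but the products share factors,
#' which makes the test anti-conservative; retained for comparison).
#' Exact p-values are used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param w1,w2 Single-knockdown fitness replicates (numeric vectors).
#' @param w12 Double-knockdown fitness replicates.
#' @param alpha Significance level.
#' @param null Construction of the expected sample: `"paired"` or
#'   `"cross-products"`.
#' @param min_replicates Minimum replicates required in each sample.
#' @return List with `p_value`, `significant`, `expected` (the expected
#'   sample used), and `method`.
#' @export
quantitative_masking_test <- function(w1, w2, w12, alpha = 0.05,
                                      null = c("paired", "cross-products"),
                                      min_replicates = 3) {
  null <- match.arg(null)
  if (length(w1) < min_replicates || length(w2) < min_replicates ||
      length(w12) < min_replicates) {
    stop("insufficient data: fewer than ", min_replicates,
         " replicates", call. = FALSE)
  }
  expected <- if (null == "paired") {
    n <- min(length(w1), length(w2))
    w1[seq_len(n)] * w2[seq_len(n)]
  } else {
    as.vector(outer(w1, w2))
  }
  pooled <- c(w12, expected)
  if (stats::var(pooled) == 0) {
    # every observation tied: no evidence either way
    return(list(p_value = 1, significant = FALSE, expected = expected,
                method = "degenerate"))
  }
  use_exact <- length(pooled) <= 20 && !anyDuplicated(pooled)
  ht <- suppressWarnings(
    stats::wilcox.test(w12, expected, alternative = "less",
                       exact = use_exact, correct = TRUE))
  list(p_value = ht$p.value,
       significant = ht$p.value < alpha,
       expected = expected,
       method = if (use_exact) "exact" else "normal approximation")
}

# Lexicographic severity score of a call set: severity rank first, then
# earliness (earlier developmental stage = more severe). Missing stages rank
# as latest. Returns c(-Inf, -Inf) for an empty call set.
.qual_score <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) return(c(-Inf, -Inf))
  stage <- calls$stage_rank
  stage[is.na(stage)] <- max(stage_ranks())
  sev <- calls$severity_rank
  best <- order(-sev, stage)[1]
  c(sev[best], -stage[best])
}

#' Qualitative masking escalation
#'
#' `TRUE` iff the double knockdown exhibits a call strictly more severe than
#' any call from either single knockdown, where severity is compared first
#' on the phenotype-class severity rank and then, within equal severity, on
#' developmental stage (an earlier stage of the same class is the more
#' severe observation, e.g. larval lethality at L1 versus L3).
#'
#' @param single_calls_1,single_calls_2,double_calls Call data frames from
#'   [assign_penetrant_calls()] (columns `severity_rank`, `stage_rank`).
#' @return Logical.
#' @export
qualitative_escalation <- function(single_calls_1, single_calls_2,
                                   double_calls) {
  s1 <- .qual_score(single_calls_1)
  s2 <- .qual_score(single_calls_2)
  d <- .qual_score(double_calls)
  best_single <- if (s1[1] > s2[1] || (s1[1] == s2[1] && s1[2] >= s2[2])) {
    s1
  } else {
    s2
  }
  d[1] > best_single[1] || (d[1] == best_single[1] && d[2] > best_single[2])
}

#' Classify a pair's masking call
#'
#' A pair shows masking when any quantitative measure is significantly
#' worse than the multiplicative expectation or the qualitative escalation
#' rule fires. Masking is "full" when neither single knockdown has any
#' penetrant phenotype call (no observable defect is found upon single-gene
#' knockdown but a defect is revealed by the double knockdown), and
#' "partial" otherwise.
#'
#' @param single_calls_1,single_calls_2 Penetrant call sets of the single
#'   knockdowns (data frames or code vectors; only emptiness is used).
#' @param quantitative_significant Logical vector, one per quantitative
#'   measure tested (from [quantitative_masking_test()]).
#' @param escalation Logical, from [qualitative_escalation()].
#' @return `"none"`, `"partial"` or `"full"`.
#' @export
classify_masking <- function(single_calls_1, single_calls_2,
                             quantitative_significant, escalation = FALSE) {
  evidence <- any(quantitative_significant) || isTRUE(escalation)
  if (!evidence) return("none")
  singles_clean <- !has_knockdown_phenotype(single_calls_1) &&
    !has_knockdown_phenotype(single_calls_2)
  if (singles_clean) "full" else "partial"
}
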