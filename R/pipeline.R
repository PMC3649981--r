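# Glue over the screen and masking modules: score one pair's masking from
# replicate-level tables, and classify a whole screened pair set.

#' Masking result for one screened pair
#'
#' Normalises each quantitative measure of the two single knockdowns and
#' the double knockdown against the control wells, tests each measure for a
#' significantly sub-multiplicative double knockdown, applies the
#' qualitative escalation rule, and classifies the pair's masking call.
#' Conditions are identified in the tables as: single wells by gene id,
#' double wells by pair id, control wells by `"control"`.
#'
#' By default the quantitative tests are only run for candidate pairs whose
#' double knockdown shows at least one penetrant phenotype call, mirroring
#' the screen protocol in which only pairs with an apparent double-knockdown
#' defect are carried into quantitative retesting; this keeps the
#' per-measure, uncorrected testing from accumulating false masking calls
#' over the vast majority of pairs whose double knockdown is
#' indistinguishable from controls.
#'
#' @param quant Quantitative table (`condition_id`, `replicate`, `measure`,
#'   `value`), e.g. from [emit_screen_tables()].
#' @param qual Qualitative table (`condition_id`, `replicate`,
#'   `generation`, `phenotype_code`, `penetrance`, `stage`).
#' @param pair_id,gene1,gene2 Condition identifiers.
#' @param alpha Per-measure significance level.
#' @param null Expected-sample construction, see
#'   [quantitative_masking_test()].
#' @param require_double_phenotype Gate the quantitative tests on the
#'   double knockdown having at least one penetrant qualitative call.
#' @return List with `pair_id`, `call` (`"none"`, `"partial"`, `"full"`),
#'   `measures` (data frame: measure, w1, w2, expected, w12, p_value,
#'   significant; p-values `NA` when the pair was not a candidate),
#'   `escalation`, `candidate`, and the single-knockdown call sets.
#' @export
pair_masking_result <- function(quant, qual, pair_id, gene1, gene2,
                                alpha = 0.05, null = "paired",
                                require_double_phenotype = TRUE) {
  w_of <- function(id, ms) {
    obs <- quant$value[quant$condition_id == id & quant$measure == ms]
    ctl <- quant$value[quant$condition_id == "control" &
                         quant$measure == ms]
    normalize_fitness(obs, ctl)
  }
  calls <- assign_penetrant_calls(qual[qual$condition_id %in%
                                         c(gene1, gene2, pair_id), ,
                                       drop = FALSE])
  calls1 <- calls[calls$condition_id == gene1, , drop = FALSE]
  calls2 <- calls[calls$condition_id == gene2, , drop = FALSE]
  callsd <- calls[calls$condition_id == pair_id, , drop = FALSE]
  candidate <- !require_double_phenotype || nrow(callsd) > 0
  measures <- sort(unique(quant$measure[quant$condition_id == pair_id]))
  res <- lapply(measures, function(ms) {
    w1 <- w_of(gene1, ms)
    w2 <- w_of(gene2, ms)
    w12 <- w_of(pair_id, ms)
    t <- if (candidate) {
      quantitative_masking_test(w1, w2, w12, alpha = alpha, null = null)
    } else {
      list(p_value = NA_real_, significant = FALSE)
    }
    data.frame(measure = ms, w1 = mean(w1), w2 = mean(w2),
               expected = expected_double(mean(w1), mean(w2)),
               w12 = mean(w12), p_value = t$p_value,
               significant = t$significant, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  esc <- candidate && qualitative_escalation(calls1, calls2, callsd)
  call <- classify_masking(calls1, calls2, res$significant, esc)
  list(pair_id = pair_id, call = call, measures = res, escalation = esc,
       candidate = candidate, single_calls_1 = calls1,
       single_calls_2 = calls2)
}

#' Score masking and essentiality for a screened pair set
#'
#' Runs [pair_masking_result()] for every pair and combines the masking
#' call with per-gene prior-screen phenotype flags into the
#' essential/non-essential classification.
#'
#' @param quant,qual Screen tables (see [pair_masking_result()]).
#' @param pairs Data frame with `pair_id`, `gene1`, `gene2`.
#' @param prior_flags Named logical vector of prior-screen single-knockdown
#'   phenotype flags per gene (`NA` = not covered).
#' @param alpha,null Passed to the masking test.
#' @return Data frame with `pair_id`, `masking_call`, `essential`
#'   (logical), `coverage_warning`.
#' @export
screen_masking_calls <- function(quant, qual, pairs, prior_flags,
                                 alpha = 0.05, null = "paired") {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- pair_masking_result(quant, qual, pairs$pair_id[i], pairs$gene1[i],
                             pairs$gene2[i], alpha = alpha, null = null)
    f1 <- prior_flags[pairs$gene1[i]]
    f2 <- prior_flags[pairs$gene2[i]]
    cls <- classify_pair_essential(unname(f1), unname(f2), r$call)
    data.frame(pair_id = pairs$pair_id[i], masking_call = r$call,
               essential = cls$class == "essential",
               coverage_warning = cls$coverage_warning,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
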