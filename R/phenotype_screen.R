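# RNAi screen phenotype scoring: brood/lethality thresholds, penetrance
# calls, knockdown-phenotype flags and essential/non-essential pair
# classification.

#' Controlled vocabulary of screen phenotype codes
#'
#' Qualitative phenotype classes scored in the knockdown screen, each with a
#' default severity rank for qualitative comparisons (higher = more severe).
#' The ordering places lethality classes above sterility/developmental
#' classes and those above milder morphological/behavioural classes; it is a
#' package default and can be overridden wherever a `vocabulary` argument is
#' accepted.
#'
#' @format Data frame with columns `code` and `severity_rank`.
#' @export
phenotype_vocabulary <- function() {
  data.frame(
    code = c("Emb", "Lvl", "Adl", "Rup", "Ste", "Stp", "Lbd", "Bmd", "Sck",
             "Prz", "Unc", "Mlt", "Bli", "Pvl", "Muv", "Egl", "Ooc", "Dpy",
             "Sma", "Lon", "Gro", "Him"),
    severity_rank = c(10L, 10L, 9L, 9L, 8L, 8L, 7L, 6L, 6L,
                      5L, 5L, 5L, 4L, 4L, 4L, 4L, 4L, 3L,
                      3L, 3L, 2L, 1L),
    stringsAsFactors = FALSE)
}

#' Developmental stage ranks
#'
#' Ranks the larval-to-adult stages used to qualify phenotype calls
#' (`L1 < L2 < L3 < L4 < Adult`); an earlier stage of the same phenotype
#' class is the more severe observation.
#'
#' @return Named integer vector of stage ranks.
#' @export
stage_ranks <- function() {
  c(L1 = 1L, L2 = 2L, L3 = 3L, L4 = 4L, Adult = 5L)
}

#' Score fertility and embryonic lethality for one well
#'
#' Mothers are sterile (`Ste`) when the well contains fewer than 10 F1
#' progeny and low-brood (`Lbd`) when it contains at least 10 but fewer than
#' 30 (so `Ste` and `Lbd` are mutually exclusive). Embryonic lethality
#' (`Emb`) is assigned when at least 10% of the brood failed to hatch;
#' to avoid calls on tiny broods, `Emb` is only evaluated when at least
#' `min_brood_for_emb` progeny were scored.
#'
#' @param brood_count Number of F1 progeny in the well.
#' @param unhatched_count Number of F1 embryos that failed to hatch.
#' @param f1_total Total F1 embryos scored for hatching.
#' @param min_brood_for_emb Minimum `f1_total` for an `Emb` call.
#' @return Character vector of phenotype codes (possibly empty).
#' @export
score_brood_and_lethality <- function(brood_count, unhatched_count,
                                      f1_total, min_brood_for_emb = 10) {
  stopifnot(length(brood_count) == 1, brood_count >= 0,
            unhatched_count >= 0, f1_total >= 0)
  if (f1_total == 0 && unhatched_count > 0) {
    stop("data inconsistency: unhatched_count > 0 with f1_total = 0",
         call. = FALSE)
  }
  if (unhatched_count > f1_total) {
    stop("data inconsistency: unhatched_count exceeds f1_total",
         call. = FALSE)
  }
  codes <- character(0)
  if (brood_count < 10) {
    codes <- c(codes, "Ste")
  } else if (brood_count < 30) {
    codes <- c(codes, "Lbd")
  }
  if (f1_total >= min_brood_for_emb &&
      unhatched_count / f1_total >= 0.10) {
    codes <- c(codes, "Emb")
  }
  codes
}

#' Assign penetrant phenotype calls from replicate observations
#'
#' A phenotype is called for a condition iff at least one replicate reaches
#' the generation-appropriate penetrance threshold: at least 10% of the F1
#' population, or at least 50% of the P0 mothers. The call carries the
#' severity rank of the phenotype class and the earliest (lowest-ranked)
#' developmental stage at which a qualifying replicate observed it.
#'
#' @param observations Data frame of qualitative replicate observations with
#'   columns `condition_id`, `phenotype_code`, `penetrance` (fraction in
#'   \[0, 1\]), `generation` (`"P0"` or `"F1"`), and optionally `stage`
#'   (`"L1"`..`"Adult"`; `NA` allowed).
#' @param vocabulary Severity table, by default [phenotype_vocabulary()].
#' @return Data frame of calls: `condition_id`, `phenotype_code`,
#'   `severity_rank`, `stage_rank` (`NA` when no stage was recorded).
#' @export
assign_penetrant_calls <- function(observations,
                                   vocabulary = phenotype_vocabulary()) {
  need <- c("condition_id", "phenotype_code", "penetrance", "generation")
  stopifnot(all(need %in% names(observations)))
  empty <- data.frame(condition_id = character(),
                      phenotype_code = character(),
                      severity_rank = integer(), stage_rank = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(observations) == 0) return(empty)
  unknown <- setdiff(unique(observations$phenotype_code), vocabulary$code)
  if (length(unknown)) {
    stop("unknown phenotype code '", unknown[1], "'", call. = FALSE)
  }
  bad_gen <- setdiff(unique(observations$generation), c("P0", "F1"))
  if (length(bad_gen)) {
    stop("unknown generation '", bad_gen[1], "'", call. = FALSE)
  }
  thr <- ifelse(observations$generation == "F1", 0.10, 0.50)
  hit <- observations[observations$penetrance >= thr, , drop = FALSE]
  if (nrow(hit) == 0) return(empty)
  sr <- stage_ranks()
  hit$stage_rank <- if ("stage" %in% names(hit)) {
    unname(sr[as.character(hit$stage)])
  } else {
    NA_integer_
  }
  key <- paste(hit$condition_id, hit$phenotype_code, sep = "\r")
  first <- hit[!duplicated(key), c("condition_id", "phenotype_code")]
  first$severity_rank <- vocabulary$severity_rank[
    match(first$phenotype_code, vocabulary$code)]
  # earliest observed stage among qualifying replicates
  min_stage <- tapply(hit$stage_rank, key, function(s) {
    s <- s[!is.na(s)]
    if (length(s)) min(s) else NA_integer_
  })
  first$stage_rank <- as.integer(min_stage[paste(first$condition_id,
                                                 first$phenotype_code,
                                                 sep = "\r")])
  rownames(first) <- NULL
  first
}

#' Does a condition show any knockdown phenotype?
#'
#' @param calls Data frame of penetrant calls for one condition (from
#'   [assign_penetrant_calls()]) or a character vector of phenotype codes.
#' @return `TRUE` iff the call set is non-empty.
#' @export
has_knockdown_phenotype <- function(calls) {
  if (is.data.frame(calls)) nrow(calls) > 0 else length(calls) > 0
}

#' Classify a duplicate pair as essential or non-essential
#'
#' A pair is essential when its double knockdown has an obvious phenotypic
#' defect, operationalised as: (i) at least one member had a knockdown
#' phenotype in the prior single-gene screens, or (ii) the pair shows
#' phenotype masking. Prior-screen flags should only be supplied for genes
#' covered by a uniquely-targeting reagent; when neither gene is covered the
#' classification is still returned but flagged.
#'
#' @param prior_flag1,prior_flag2 Logical prior-screen phenotype flags for
#'   the two genes (`NA` = gene not covered by a unique reagent).
#' @param masking_call One of `"none"`, `"partial"`, `"full"`.
#' @return List with `class` (`"essential"` or `"non_essential"`) and
#'   `coverage_warning` (`TRUE` when both prior flags are `NA`).
#' @export
classify_pair_essential <- function(prior_flag1, prior_flag2, masking_call) {
  masking_call <- match.arg(masking_call, c("none", "partial", "full"))
  coverage_warning <- is.na(prior_flag1) && is.na(prior_flag2)
  prior <- isTRUE(prior_flag1) || isTRUE(prior_flag2)
  list(class = if (prior || masking_call != "none") "essential"
       else "non_essential",
       coverage_warning = coverage_warning)
}

#' Concordance of phenotype calls between two screens
#'
#' The fraction of genes positive in the reference screen `calls_b` that are
#' also positive in screen `calls_a` (computed over genes present in both).
#'
#' @param calls_a,calls_b Named logical vectors of per-gene phenotype flags;
#'   `calls_b` is the reference set.
#' @return Fraction in `[0, 1]`.
#' @export
concordance <- function(calls_a, calls_b) {
  ref <- names(calls_b)[calls_b]
  ref <- intersect(ref, names(calls_a))
  if (length(ref) == 0) {
    stop("empty reference set: no reference-positive genes shared with ",
         "screen a", call. = FALSE)
  }
  mean(calls_a[ref])
}

#' Read a replicate-level screen table
#'
#' Reads a TSV of well observations with at least the columns
#' `condition_id`, `replicate`, `generation`, plus count and/or qualitative
#' columns as produced by [emit_screen_tables()].
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_screen_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}
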