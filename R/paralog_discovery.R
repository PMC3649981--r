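# Paralog discovery from all-vs-all protein similarity searches:
# reciprocal-best-hit pairs, single-copy genes, the duplicate isolation
# value, and RNAi probe target specificity.

#' Read protein lengths from a FASTA file
#'
#' Sequence lengths are needed to convert HSP spans into per-protein
#' coverage fractions. Use the longest isoform per gene upstream; names are
#' taken from the first whitespace-delimited token of each FASTA header.
#'
#' @param path Path to a protein FASTA file.
#' @return Named integer vector of protein lengths.
#' @export
read_protein_lengths <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  len <- Biostrings::width(seqs)
  names(len) <- sub("\\s.*$", "", names(seqs))
  len
}

#' Read a tabular alignment hit table
#'
#' Parses the standard 12-column tabular output of a protein similarity
#' search (qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore). Self-hits are removed, multiple HSPs per directed
#' gene pair are reduced to the single best HSP (smallest e-value, ties by
#' larger bitscore), and per-side coverage is computed as the HSP span
#' divided by the protein length.
#'
#' @param path Path to the tabular hit file.
#' @param protein_lengths Named numeric vector of protein lengths covering
#'   every gene id in the table (see [read_protein_lengths()]).
#' @return A data frame of directed hits with columns `query_id`,
#'   `subject_id`, `evalue`, `bitscore`, `qcov`, `scov`.
#' @export
read_hit_table <- function(path, protein_lengths) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, col.names = cols,
                      colClasses = c("character", "character",
                                     rep("numeric", 10)),
                      comment.char = "#", quote = ""),
    error = function(e) stop("malformed hit table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(raw) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      qcov = numeric(), scov = numeric(),
                      stringsAsFactors = FALSE))
  }
  bad <- which(!is.finite(raw$evalue) | raw$evalue < 0)
  if (length(bad)) {
    stop("malformed hit table row ", bad[1], ": bad e-value", call. = FALSE)
  }
  raw <- raw[raw$query_id != raw$subject_id, , drop = FALSE]
  genes <- unique(c(raw$query_id, raw$subject_id))
  missing <- setdiff(genes, names(protein_lengths))
  if (length(missing)) {
    stop("missing protein length for gene '", missing[1], "'", call. = FALSE)
  }
  # best HSP per directed pair: smallest e-value, then largest bitscore
  ord <- order(raw$query_id, raw$subject_id, raw$evalue, -raw$bitscore)
  raw <- raw[ord, , drop = FALSE]
  key <- paste(raw$query_id, raw$subject_id, sep = "\r")
  raw <- raw[!duplicated(key), , drop = FALSE]
  data.frame(
    query_id = raw$query_id,
    subject_id = raw$subject_id,
    evalue = raw$evalue,
    bitscore = raw$bitscore,
    qcov = abs(raw$qend - raw$qstart + 1) /
      as.numeric(protein_lengths[raw$query_id]),
    scov = abs(raw$send - raw$sstart + 1) /
      as.numeric(protein_lengths[raw$subject_id]),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Best non-self hit per query under the deterministic tie-break:
# smallest e-value, then largest bitscore, then lexicographic subject id.
.best_hits <- function(hits) {
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Identify reciprocal-best-hit duplicate pairs
#'
#' A pair (A, B) is emitted iff B is A's best-scoring non-self hit and A is
#' B's best-scoring non-self hit, both directed hits have
#' `evalue < max_evalue`, and the HSP spans cover at least `min_cov` of each
#' protein on both sides. Mutual-best pairs are disjoint in genes by
#' construction. The pair e-value is the more significant (smaller) of the
#' two directed e-values.
#'
#' @param hits Directed hit table from [read_hit_table()].
#' @param max_evalue Significance threshold applied to both directed hits.
#' @param min_cov Minimum coverage fraction required of both `qcov` and
#'   `scov` in both directions.
#' @return Data frame with columns `gene1`, `gene2` (canonically ordered
#'   `gene1 < gene2`) and `pair_evalue`.
#' @export
reciprocal_best_pairs <- function(hits, max_evalue = 1e-9, min_cov = 0.60) {
  empty <- data.frame(gene1 = character(), gene2 = character(),
                      pair_evalue = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  best <- .best_hits(hits)
  mate <- stats::setNames(best$subject_id, best$query_id)
  a <- best$query_id
  b <- best$subject_id
  mutual <- !is.na(mate[b]) & mate[b] == a & a < b
  cand <- best[mutual, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  back <- best[match(cand$subject_id, best$query_id), , drop = FALSE]
  ok <- cand$evalue < max_evalue & back$evalue < max_evalue &
    cand$qcov >= min_cov & cand$scov >= min_cov &
    back$qcov >= min_cov & back$scov >= min_cov
  cand <- cand[ok, , drop = FALSE]
  back <- back[ok, , drop = FALSE]
  out <- data.frame(gene1 = cand$query_id, gene2 = cand$subject_id,
                    pair_evalue = pmin(cand$evalue, back$evalue),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene1, out$gene2), , drop = FALSE]
}

#' Classify single-copy genes
#'
#' Single-copy genes are those without any non-self hit, in either
#' direction, more significant than `max_evalue`.
#'
#' @param hits Directed hit table.
#' @param genes Character vector: the full gene universe.
#' @param max_evalue E-value threshold (a hit with `evalue < max_evalue`
#'   disqualifies a gene).
#' @return Character vector of single-copy gene ids.
#' @export
classify_single_copy <- function(hits, genes, max_evalue = 0.01) {
  sig <- hits[hits$evalue < max_evalue, , drop = FALSE]
  hit_genes <- unique(c(sig$query_id, sig$subject_id))
  setdiff(genes, hit_genes)
}

# Symmetric best e-value per unordered gene pair: the minimum over the
# (up to two) directed hits between the genes. Zero e-values are clamped so
# logs stay finite.
.pair_evalue_lookup <- function(hits, clamp = 1e-180) {
  g1 <- pmin(hits$query_id, hits$subject_id)
  g2 <- pmax(hits$query_id, hits$subject_id)
  ev <- pmax(hits$evalue, clamp)
  key <- paste(g1, g2, sep = "\r")
  tapply(ev, key, min)
}

#' Duplicate isolation value
#'
#' Measures how close a duplicate pair's nearest shared hit is, relative to
#' the similarity within the pair, on a negative-log10-e-value scale.
#' Candidate shared hits are third genes hit by both members at
#' `evalue < shared_max_evalue`; the closest shared hit minimises the
#' maximum of its two e-values. The value is
#' `(-log10 shared) / (-log10 pair_evalue)`, clamped to `[0, 1]`; it is 0
#' when the pair has no shared hit (a two-member family) and approaches 1
#' when a third paralog is as close as the pair itself.
#'
#' @param gene1,gene2 The two members of the pair.
#' @param hits Directed hit table.
#' @param shared_max_evalue Candidacy threshold for shared third-gene hits.
#' @param clamp_evalue Underflowed e-values (0) are clamped to this before
#'   taking logs.
#' @return A single numeric isolation value in `[0, 1]`.
#' @export
isolation_value <- function(gene1, gene2, hits, shared_max_evalue = 0.01,
                            clamp_evalue = 1e-180) {
  lut <- .pair_evalue_lookup(hits, clamp = clamp_evalue)
  .isolation_one(gene1, gene2, lut, shared_max_evalue)
}

.isolation_one <- function(gene1, gene2, lut, shared_max_evalue) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pe <- lut[key(gene1, gene2)]
  if (is.na(pe)) {
    stop("no hit between '", gene1, "' and '", gene2, "' in the hit table",
         call. = FALSE)
  }
  keys <- names(lut)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ka <- vapply(parts, `[[`, "", 1L)
  kb <- vapply(parts, `[[`, "", 2L)
  third_of <- function(g) {
    sel <- (ka == g | kb == g) & lut < shared_max_evalue
    t <- ifelse(ka[sel] == g, kb[sel], ka[sel])
    stats::setNames(lut[sel], t)
  }
  t1 <- third_of(gene1)
  t2 <- third_of(gene2)
  shared <- setdiff(intersect(names(t1), names(t2)), c(gene1, gene2))
  if (length(shared) == 0) return(0)
  score <- pmax(t1[shared], t2[shared])
  best <- min(score)
  iso <- (-log10(best)) / (-log10(pe))
  unname(min(max(iso, 0), 1))
}

#' Annotate a pair table with isolation values
#'
#' @param pairs Data frame with `gene1`, `gene2` (e.g. from
#'   [reciprocal_best_pairs()]).
#' @inheritParams isolation_value
#' @return `pairs` with an added `isolation` column.
#' @export
add_isolation <- function(pairs, hits, shared_max_evalue = 0.01,
                          clamp_evalue = 1e-180) {
  lut <- .pair_evalue_lookup(hits, clamp = clamp_evalue)
  pairs$isolation <- vapply(seq_len(nrow(pairs)), function(i) {
    .isolation_one(pairs$gene1[i], pairs$gene2[i], lut, shared_max_evalue)
  }, numeric(1))
  pairs
}

#' Filter pairs on the duplicate isolation value
#'
#' Retains pairs without a close third paralog: `isolation <= cutoff`
#' (the cutoff is inclusive).
#'
#' @param pairs Data frame with an `isolation` column.
#' @param cutoff Inclusive upper bound on isolation.
#' @return The retained subset of `pairs`.
#' @export
filter_isolated_pairs <- function(pairs, cutoff = 0.83) {
  if (is.null(pairs$isolation)) {
    stop("pairs lack an 'isolation' column; run add_isolation() first",
         call. = FALSE)
  }
  pairs[pairs$isolation <= cutoff, , drop = FALSE]
}

#' Classify RNAi probe targets as primary or secondary
#'
#' A gene is a primary target of a probe if any identity segment has at
#' least 95% nucleotide identity over at least 100 bp; otherwise a
#' secondary target if any segment has at least 80% identity over at least
#' 200 bp; otherwise not a target.
#'
#' @param segments Data frame with columns `probe_id`, `gene_id`,
#'   `identity` (fraction in \[0, 1\]) and `span_bp`.
#' @return Data frame `probe_id`, `gene_id`, `class` with class in
#'   `{"primary", "secondary", "none"}`.
#' @export
probe_target_classes <- function(segments) {
  stopifnot(all(c("probe_id", "gene_id", "identity", "span_bp") %in%
                  names(segments)))
  key <- paste(segments$probe_id, segments$gene_id, sep = "\r")
  prim <- tapply(segments$identity >= 0.95 & segments$span_bp >= 100,
                 key, any)
  seco <- tapply(segments$identity >= 0.80 & segments$span_bp >= 200,
                 key, any)
  ids <- strsplit(names(prim), "\r", fixed = TRUE)
  data.frame(
    probe_id = vapply(ids, `[[`, "", 1L),
    gene_id = vapply(ids, `[[`, "", 2L),
    class = ifelse(prim, "primary", ifelse(seco, "secondary", "none")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Retain pairs in which each member is uniquely targetable
#'
#' A probe is "clean" for a gene when its target map contains exactly one
#' primary target (that gene) and no secondary targets. A pair is retained
#' when both members have at least one clean probe.
#'
#' @param pairs Data frame with `gene1`, `gene2`.
#' @param segments Probe identity segments (see [probe_target_classes()]).
#' @return The retained subset of `pairs`.
#' @export
uniquely_targetable_pairs <- function(pairs, segments) {
  cls <- probe_target_classes(segments)
  cls <- cls[cls$class != "none", , drop = FALSE]
  clean_gene <- character(0)
  for (p in unique(cls$probe_id)) {
    sub <- cls[cls$probe_id == p, , drop = FALSE]
    prim <- sub$gene_id[sub$class == "primary"]
    seco <- sub$gene_id[sub$class == "secondary"]
    if (length(prim) == 1 && length(seco) == 0) {
      clean_gene <- c(clean_gene, prim)
    }
  }
  clean_gene <- unique(clean_gene)
  keep <- pairs$gene1 %in% clean_gene & pairs$gene2 %in% clean_gene
  pairs[keep, , drop = FALSE]
}

#' Write a duplicate-pair table to TSV
#'
#' @param pairs Pair data frame (any columns; `gene1`/`gene2` required).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
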