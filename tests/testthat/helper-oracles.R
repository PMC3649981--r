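# Brute-force oracles, kept independent of the package implementation:
# used to freeze expected values and to check the fast paths on small
# random inputs.

# Exhaustive mutual-best search over all unordered gene pairs.
rbh_oracle <- function(hits, max_evalue = 1e-9, min_cov = 0.60) {
  genes <- sort(unique(c(hits$query_id, hits$subject_id)))
  best_of <- function(g) {
    h <- hits[hits$query_id == g, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h <- h[order(h$evalue, -h$bitscore, h$subject_id), , drop = FALSE]
    h[1, , drop = FALSE]
  }
  out <- NULL
  for (a in genes) {
    for (b in genes) {
      if (a >= b) next
      ba <- best_of(a)
      bb <- best_of(b)
      if (is.null(ba) || is.null(bb)) next
      if (ba$subject_id != b || bb$subject_id != a) next
      if (!(ba$evalue < max_evalue && bb$evalue < max_evalue)) next
      if (!(ba$qcov >= min_cov && ba$scov >= min_cov &&
            bb$qcov >= min_cov && bb$scov >= min_cov)) next
      out <- rbind(out, data.frame(gene1 = a, gene2 = b,
                                   pair_evalue = min(ba$evalue, bb$evalue),
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    data.frame(gene1 = character(), gene2 = character(),
               pair_evalue = numeric(), stringsAsFactors = FALSE)
  } else {
    out[order(out$gene1, out$gene2), , drop = FALSE]
  }
}

# Random directed hit table over n genes for oracle-equivalence checks.
random_hit_table <- function(n_genes, density = 0.4) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  rows <- NULL
  for (a in genes) {
    for (b in setdiff(genes, a)) {
      if (stats::runif(1) > density) next
      rows <- rbind(rows, data.frame(
        query_id = a, subject_id = b,
        evalue = 10^stats::runif(1, -60, 0),
        bitscore = stats::runif(1, 50, 500),
        qcov = stats::runif(1, 0.3, 1),
        scov = stats::runif(1, 0.3, 1),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(query_id = character(), subject_id = character(),
                       evalue = numeric(), bitscore = numeric(),
                       qcov = numeric(), scov = numeric(),
                       stringsAsFactors = FALSE)
  }
  rows
}

# Exact one-sided rank-test p-value by enumeration of all assignments of
# the pooled sample to the two groups (no ties assumed).
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  idx <- utils::combn(length(pooled), length(x))
  w_all <- apply(idx, 2, function(i) sum(r[i]))
  mean(w_all <= w_obs)
}

# Two-sided Fisher p-value by hypergeometric enumeration (R's convention:
# sum of table probabilities not exceeding the observed, with relative
# tolerance).
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# LCA by path intersection: walk each tip's ancestor path to the root; the
# LCA is the first shared node on the first tip's path.
lca_oracle <- function(tree, tip1, tip2) {
  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p) == 0) NA_integer_ else p
  }
  path_up <- function(tip) {
    node <- which(tree$tip.label == tip)
    path <- integer(0)
    while (!is.na(node)) {
      path <- c(path, node)
      node <- parent_of(node)
    }
    path
  }
  p1 <- path_up(tip1)
  p2 <- path_up(tip2)
  p1[p1 %in% p2][1]
}

# Degeneracy class of a codon position derived through seqinr's genetic
# code machinery (an implementation path independent of the package's).
degeneracy_oracle <- function(codon, position) {
  translate1 <- function(cod) {
    seqinr::translate(strsplit(tolower(cod), "")[[1]])
  }
  aa <- translate1(codon)
  nsyn <- 0L
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon, position,
                                                  position))) {
    alt <- codon
    substr(alt, position, position) <- b
    if (translate1(alt) == aa) nsyn <- nsyn + 1L
  }
  if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
}

# All 61 sense codons.
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Small helper to build a directed hit data frame from triples.
make_hits <- function(q, s, evalue, bitscore = 100, qcov = 0.9,
                      scov = 0.9) {
  data.frame(query_id = q, subject_id = s, evalue = evalue,
             bitscore = bitscore, qcov = qcov, scov = scov,
             stringsAsFactors = FALSE)
}
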