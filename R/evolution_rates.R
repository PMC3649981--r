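# Nonsynonymous divergence (Ka) between codon-aligned sequences by Li's
# 1993 protocol: site degeneracy classification, transition/transversion
# counting per class, Kimura two-parameter multiple-hit correction, and the
# unbiased combination across nondegenerate and twofold sites.

.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

.deg_env <- new.env(parent = emptyenv())

# 61 sense codons x 3 positions: number of synonymous changes among the 3
# alternative bases determines the class (0 -> nondegenerate, 1-2 ->
# twofold, 3 -> fourfold). Changes to stop codons count as nonsynonymous.
.degeneracy_table <- function() {
  if (!is.null(.deg_env$tab)) return(.deg_env$tab)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  tab <- matrix(NA_integer_, nrow = length(sense), ncol = 3,
                dimnames = list(sense, NULL))
  for (cod in sense) {
    aa <- gc[[cod]]
    for (pos in 1:3) {
      alt <- setdiff(.BASES, substr(cod, pos, pos))
      nsyn <- 0L
      for (b in alt) {
        c2 <- cod
        substr(c2, pos, pos) <- b
        if (gc[[c2]] == aa) nsyn <- nsyn + 1L
      }
      tab[cod, pos] <- if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
    }
  }
  .deg_env$tab <- tab
  tab
}

#' Degeneracy class of a codon position
#'
#' Classifies a position of a sense codon as nondegenerate (0-fold),
#' twofold or fourfold degenerate under the standard genetic code, with
#' Li's conventions: a position is nondegenerate when no single-base change
#' is synonymous, fourfold when all three are, and twofold otherwise (this
#' folds the isoleucine third position and the arginine/leucine first-position
#' irregularities into the twofold class).
#'
#' @param codon A sense codon string over `ACGT`.
#' @param position 1, 2 or 3.
#' @return Integer: 0, 2 or 4.
#' @export
classify_site_degeneracy <- function(codon, position) {
  tab <- .degeneracy_table()
  codon <- toupper(codon)
  if (!codon %in% rownames(tab)) {
    stop("'", codon, "' is not a sense codon", call. = FALSE)
  }
  stopifnot(position %in% 1:3)
  unname(tab[codon, position])
}

.is_transition <- function(a, b) .TS_PARTNER[a] == b

# Split aligned sequences into codon triplets; returns a character matrix
# with one row per codon, columns pos1..pos3.
.codon_matrix <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  matrix(s, ncol = 3, byrow = TRUE)
}

#' Count degeneracy-class sites and differences for a codon alignment
#'
#' Walks a pairwise codon alignment and accumulates, per degeneracy class
#' (0-fold, 2-fold, 4-fold): the average number of sites over the two
#' sequences (`L0`, `L2`, `L4`) and the proportions of transitional (`P`)
#' and transversional (`Q`) differences. When the two sequences assign a
#' position to different classes, the site and any difference at it
#' contribute half weight to each class. Codons containing gaps, ambiguity
#' characters or stop codons in either sequence are excluded pairwise.
#'
#' @param seq1,seq2 Aligned nucleotide strings of equal length divisible by
#'   3, over `ACGT-` (other characters are treated as ambiguous).
#' @return List with `L0`, `L2`, `L4`, `P0`, `P2`, `P4`, `Q0`, `Q2`, `Q4`
#'   and `n_codons_used`.
#' @export
count_site_classes_and_differences <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  if (nchar(seq1) %% 3 != 0) {
    stop("alignment length must be divisible by 3", call. = FALSE)
  }
  tab <- .degeneracy_table()
  m1 <- .codon_matrix(seq1)
  m2 <- .codon_matrix(seq2)
  c1 <- apply(m1, 1, paste, collapse = "")
  c2 <- apply(m2, 1, paste, collapse = "")
  ok <- c1 %in% rownames(tab) & c2 %in% rownames(tab)
  if (!any(ok)) {
    stop("no comparable codons after excluding gapped/ambiguous/stop codons",
         call. = FALSE)
  }
  c1 <- c1[ok]
  c2 <- c2[ok]
  m1 <- m1[ok, , drop = FALSE]
  m2 <- m2[ok, , drop = FALSE]
  cls <- c("0", "2", "4")
  L <- stats::setNames(numeric(3), cls)
  ts <- L
  tv <- L
  for (pos in 1:3) {
    k1 <- as.character(tab[c1, pos])
    k2 <- as.character(tab[c2, pos])
    for (k in cls) {
      L[k] <- L[k] + 0.5 * sum(k1 == k) + 0.5 * sum(k2 == k)
    }
    b1 <- m1[, pos]
    b2 <- m2[, pos]
    diff <- b1 != b2
    if (any(diff)) {
      is_ts <- .is_transition(b1[diff], b2[diff])
      for (k in cls) {
        w <- 0.5 * (k1[diff] == k) + 0.5 * (k2[diff] == k)
        ts[k] <- ts[k] + sum(w * is_ts)
        tv[k] <- tv[k] + sum(w * !is_ts)
      }
    }
  }
  P <- ifelse(L > 0, ts / L, 0)
  Q <- ifelse(L > 0, tv / L, 0)
  list(L0 = unname(L["0"]), L2 = unname(L["2"]), L4 = unname(L["4"]),
       P0 = unname(P["0"]), P2 = unname(P["2"]), P4 = unname(P["4"]),
       Q0 = unname(Q["0"]), Q2 = unname(Q["2"]), Q4 = unname(Q["4"]),
       n_codons_used = length(c1))
}

#' Kimura two-parameter distance components
#'
#' Given the proportions of transitional (`P`) and transversional (`Q`)
#' differences at a site class, returns the transitional component
#' `A = -1/2 ln(1 - 2P - Q) + 1/4 ln(1 - 2Q)` and the transversional
#' component `B = -1/2 ln(1 - 2Q)` of the multiple-hit-corrected distance.
#' When a log argument is non-positive the class is saturated and the
#' components are `NA`.
#'
#' @param P,Q Transition and transversion difference proportions.
#' @return List with `A`, `B`, `saturated`.
#' @export
k2p_components <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    return(list(A = NA_real_, B = NA_real_, saturated = TRUE))
  }
  list(A = -0.5 * log(a1) + 0.25 * log(a2),
       B = -0.5 * log(a2),
       saturated = FALSE)
}

#' Nonsynonymous divergence by Li's 1993 protocol
#'
#' Combines the per-class Kimura two-parameter components into the unbiased
#' nonsynonymous distance
#' `Ka = A0 + (L0*B0 + L2*B2) / (L0 + L2)`
#' (transitions at twofold sites are synonymous; transversions at twofold
#' sites and all changes at nondegenerate sites are nonsynonymous). The
#' synonymous companion `Ks = B4 + (L2*A2 + L4*A4) / (L2 + L4)` is reported
#' alongside when computable.
#'
#' @param counts Site counts from [count_site_classes_and_differences()].
#' @return List with `ka`, `ks`, `n_codons_used`, `saturated`. `ka` is `NA`
#'   with `saturated = TRUE` when any required log argument is non-positive;
#'   `ks` is `NA` if its own components saturate.
#' @export
ka_li93 <- function(counts) {
  if (counts$L0 + counts$L2 <= 0) {
    stop("no nondegenerate or twofold sites to estimate Ka from",
         call. = FALSE)
  }
  k0 <- k2p_components(counts$P0, counts$Q0)
  k2 <- k2p_components(counts$P2, counts$Q2)
  k4 <- k2p_components(counts$P4, counts$Q4)
  sat_ka <- k0$saturated || (counts$L2 > 0 && k2$saturated)
  ka <- if (sat_ka) NA_real_ else {
    b2 <- if (counts$L2 > 0) k2$B else 0
    k0$A + (counts$L0 * k0$B + counts$L2 * b2) / (counts$L0 + counts$L2)
  }
  sat_ks <- k4$saturated || (counts$L2 > 0 && k2$saturated) ||
    counts$L2 + counts$L4 <= 0
  ks <- if (sat_ks) NA_real_ else {
    a2 <- if (counts$L2 > 0) k2$A else 0
    k4$B + (counts$L2 * a2 + counts$L4 * k4$A) / (counts$L2 + counts$L4)
  }
  list(ka = ka, ks = ks, n_codons_used = counts$n_codons_used,
       saturated = sat_ka)
}

#' Ka between two aligned coding sequences
#'
#' Convenience wrapper: site counting followed by the Li-1993 estimate.
#'
#' @inheritParams count_site_classes_and_differences
#' @return See [ka_li93()].
#' @export
ka_pair <- function(seq1, seq2) {
  ka_li93(count_site_classes_and_differences(seq1, seq2))
}

#' Mean ortholog divergence for a duplicate pair
#'
#' The evolutionary rate of a duplicate pair is summarised as the arithmetic
#' mean of the Ka values of its two cross-species ortholog alignments.
#'
#' @param alignment1,alignment2 Each a list or character vector of two
#'   aligned nucleotide strings (one ortholog comparison per pair member).
#' @return Numeric mean Ka; `NA` if either estimate is saturated.
#' @export
ka_cecb <- function(alignment1, alignment2) {
  if (is.null(alignment1) || is.null(alignment2)) {
    stop("partial data: both ortholog alignments are required",
         call. = FALSE)
  }
  get2 <- function(a) {
    a <- unlist(a, use.names = FALSE)
    if (length(a) != 2) {
      stop("each ortholog alignment must contain exactly two sequences",
           call. = FALSE)
    }
    a
  }
  a <- get2(alignment1)
  b <- get2(alignment2)
  ka1 <- ka_pair(a[1], a[2])$ka
  ka2 <- ka_pair(b[1], b[2])$ka
  if (is.na(ka1) || is.na(ka2)) return(NA_real_)
  mean(c(ka1, ka2))
}

#' Read pairwise codon alignments from FASTA
#'
#' Sequences are taken two at a time in file order: records 1 and 2 form
#' the first alignment, 3 and 4 the second, and so on.
#'
#' @param path FASTA file of aligned nucleotide sequences (gaps allowed).
#' @return Named list of two-element character vectors; list names are the
#'   first record's name up to the first `|`, pair index otherwise.
#' @export
read_codon_alignments <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) %% 2 != 0) {
    stop("paired FASTA must contain an even number of records",
         call. = FALSE)
  }
  n <- length(seqs) / 2
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s1 <- as.character(seqs[[2 * i - 1]])
    s2 <- as.character(seqs[[2 * i]])
    out[[i]] <- c(s1, s2)
    nm <- sub("\\|.*$", "", names(seqs)[2 * i - 1])
    names(out)[i] <- if (nzchar(nm)) nm else as.character(i)
  }
  out
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Plumbing utility: threads ungapped CDS through an aligned protein pair,
#' inserting `---` for gap columns, producing a codon alignment suitable for
#' [ka_pair()].
#'
#' @param protein_aln Character vector of two aligned protein strings.
#' @param cds Character vector of the two ungapped coding sequences (without
#'   stop codons, or with; trailing bases beyond the protein are dropped).
#' @return Character vector of two aligned nucleotide strings.
#' @export
backtranslate_alignment <- function(protein_aln, cds) {
  stopifnot(length(protein_aln) == 2, length(cds) == 2)
  thread <- function(p, n) {
    aa <- strsplit(p, "")[[1]]
    out <- character(length(aa))
    at <- 1L
    for (i in seq_along(aa)) {
      if (aa[i] == "-") {
        out[i] <- "---"
      } else {
        out[i] <- substr(n, at, at + 2L)
        at <- at + 3L
      }
    }
    paste(out, collapse = "")
  }
  c(thread(protein_aln[1], cds[1]), thread(protein_aln[2], cds[2]))
}
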