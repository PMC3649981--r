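# Synthetic-data generator: duplication histories with essentiality-biased
# duplication and retention, expression-linked divergence, codon-alignment
# pairs with a known nonsynonymous target, bootstrap-annotated gene trees,
# and replicate-level knockdown screen tables -- all with ground truth, so
# every analysis stage can be exercised end to end.

#' Simulation parameters
#'
#' Builds and validates the parameter set for the generator. The defaults
#' encode the study conditions the generator is meant to emulate: a 17.7%
#' baseline single-gene knockdown phenotype rate, a five-fold bias towards
#' successful duplication of non-essential genes, a three-fold bias towards
#' long-term loss of non-essential duplicates, 5 replicate wells per
#' condition with 10% measurement noise, and 111 control wells.
#'
#' @param n_genes Size of the parental gene pool.
#' @param p_essential Fraction of the pool with a knockdown phenotype.
#' @param duplication_bias Ratio of duplication-fixation rates,
#'   non-essential : essential (beta > 1 encodes the duplication bias).
#' @param retention_bias Ratio of per-epoch loss rates,
#'   non-essential : essential (gamma > 1 encodes the retention bias).
#' @param epoch_events Named integer vector of duplication events per epoch;
#'   names must be the classes of [age_classes()].
#' @param loss_rate_essential Per-epoch loss probability of an essential
#'   pair; non-essential pairs lose at `min(gamma * rate, 0.99)`.
#' @param masking_decay Decay rate lambda of masking with divergence:
#'   a surviving essential pair is masked with probability
#'   `exp(-lambda * Ka)`.
#' @param masking_strength Multiplier `m < 1` applied to the multiplicative
#'   expectation of a masked pair's double knockdown.
#' @param replicate_count Replicates per screened condition (3-5).
#' @param noise_cv Coefficient of variation of replicate measures.
#' @param n_controls Number of control wells.
#' @param n_codons Codons per emitted alignment.
#' @param tstv Transition/transversion ratio of the sequence simulator.
#' @param third_paralog_rate Fraction of pairs given an injected third
#'   paralog in the emitted hit table (exercises isolation filtering).
#' @param expr_log2_mean_essential,expr_log2_mean_nonessential,expr_log2_sd
#'   Log2-normal expression model per essentiality class.
#' @param base_ka Named numeric vector: age-class scale of divergence.
#' @param expr_ka_slope Log2-expression effect on the divergence rate
#'   (divergence halves per `1/expr_ka_slope` doublings of expression).
#' @param seed Mandatory random seed.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 5000,
                       p_essential = 0.177,
                       duplication_bias = 5,
                       retention_bias = 3,
                       epoch_events = c(Eukaryota = 500, Bilateria = 500,
                                        Caenorhabditis = 500,
                                        Celegans = 500),
                       loss_rate_essential = 0.15,
                       masking_decay = 4,
                       masking_strength = 0.3,
                       replicate_count = 5,
                       noise_cv = 0.10,
                       n_controls = 111,
                       n_codons = 300,
                       tstv = 2,
                       third_paralog_rate = 0.10,
                       expr_log2_mean_essential = 11.66,
                       expr_log2_mean_nonessential = 8.60,
                       expr_log2_sd = 2,
                       base_ka = c(Celegans = 0.05, Caenorhabditis = 0.15,
                                   Bilateria = 0.45, Eukaryota = 0.80),
                       expr_ka_slope = 0.25,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory", call. = FALSE)
  }
  p <- list(n_genes = n_genes, p_essential = p_essential,
            duplication_bias = duplication_bias,
            retention_bias = retention_bias, epoch_events = epoch_events,
            loss_rate_essential = loss_rate_essential,
            masking_decay = masking_decay,
            masking_strength = masking_strength,
            replicate_count = replicate_count, noise_cv = noise_cv,
            n_controls = n_controls, n_codons = n_codons, tstv = tstv,
            third_paralog_rate = third_paralog_rate,
            expr_log2_mean_essential = expr_log2_mean_essential,
            expr_log2_mean_nonessential = expr_log2_mean_nonessential,
            expr_log2_sd = expr_log2_sd, base_ka = base_ka,
            expr_ka_slope = expr_ka_slope, seed = as.integer(seed))
  if (p$p_essential < 0 || p$p_essential > 1) {
    stop("p_essential must be in [0, 1]", call. = FALSE)
  }
  if (p$duplication_bias <= 0 || p$retention_bias <= 0) {
    stop("bias ratios must be positive", call. = FALSE)
  }
  if (!setequal(names(p$epoch_events), age_classes())) {
    stop("epoch_events must be named by the four age classes",
         call. = FALSE)
  }
  if (p$loss_rate_essential < 0 || p$loss_rate_essential >= 1) {
    stop("loss_rate_essential must be in [0, 1)", call. = FALSE)
  }
  if (p$masking_strength <= 0 || p$masking_strength >= 1) {
    stop("masking_strength must be in (0, 1)", call. = FALSE)
  }
  if (p$replicate_count < 3) {
    stop("replicate_count must be at least 3", call. = FALSE)
  }
  if (p$noise_cv < 0 || p$noise_cv > 1) {
    stop("noise_cv must be in [0, 1]", call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

# Elapsed epochs between a pair's origin and the present, by age class.
.elapsed_epochs <- function() {
  stats::setNames(c(0L, 1L, 2L, 3L), age_classes())
}

#' Closed-form essential fraction among surviving pairs, by age class
#'
#' Under the generative model, a duplication event picks an essential parent
#' with probability `p / (p + beta (1 - p))`, and a pair from a class with
#' `e` elapsed epochs survives with probability `(1 - l)^e` (essential) or
#' `(1 - min(gamma l, 0.99))^e` (non-essential). Bayes' rule then gives the
#' expected essential fraction among survivors of each class. With
#' `beta = gamma = 1` every class equals `p_essential`; with `beta > 1`
#' young pairs are depleted of essential pairs and with `gamma > 1` old
#' pairs are enriched relative to young ones.
#'
#' @param params A [sim_params()] object.
#' @return Data frame with `age_class`, `elapsed`, `expected_essential`,
#'   `expected_survivors` (expected surviving pair count of the class).
#' @export
essential_fraction_expectation <- function(params) {
  p <- params$p_essential
  beta <- params$duplication_bias
  le <- params$loss_rate_essential
  ln <- min(params$retention_bias * le, 0.99)
  p_parent <- p / (p + beta * (1 - p))
  el <- .elapsed_epochs()
  se <- (1 - le)^el
  sn <- (1 - ln)^el
  frac <- p_parent * se / (p_parent * se + (1 - p_parent) * sn)
  events <- params$epoch_events[names(el)]
  data.frame(age_class = names(el),
             elapsed = unname(el),
             expected_essential = unname(frac),
             expected_survivors = unname(events *
               (p_parent * se + (1 - p_parent) * sn)),
             stringsAsFactors = FALSE)
}

#' Simulate a duplication history with known ground truth
#'
#' Draws a parental gene pool, then, epoch by epoch from oldest to
#' youngest, duplication events whose parents are chosen with weight
#' `duplication_bias` for non-essential genes; each pair then survives the
#' epochs between its origin and the present, with non-essential pairs lost
#' `retention_bias`-fold faster. Surviving pairs accrue divergence with age
#' and inversely with expression, and essential pairs retain masking with
#' probability decaying in divergence. Non-masked essential pairs carry the
#' phenotype on one or both single knockdowns; masked pairs are fully
#' masked (no single-knockdown phenotype; the double falls below the
#' multiplicative expectation by `masking_strength`).
#'
#' @param params A [sim_params()] object (its `seed` is used).
#' @return List with `genes` (gene_id, species, essential,
#'   single_phenotype, expression_log2, protein_length), `pairs` (pair_id,
#'   gene1, gene2, age_class, essential, masked, ka_true, w1, w2, w12) and
#'   `params`.
#' @export
simulate_history <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  pool_ess <- stats::runif(n) < params$p_essential
  pool_expr <- stats::rnorm(
    n,
    ifelse(pool_ess, params$expr_log2_mean_essential,
           params$expr_log2_mean_nonessential),
    params$expr_log2_sd)

  w_parent <- ifelse(pool_ess, 1, params$duplication_bias)
  le <- params$loss_rate_essential
  ln <- min(params$retention_bias * le, 0.99)
  el <- .elapsed_epochs()

  classes <- rev(age_classes())  # oldest first
  rows <- list()
  for (cl in classes) {
    n_ev <- params$epoch_events[[cl]]
    if (n_ev == 0) next
    parent <- sample.int(n, n_ev, replace = TRUE, prob = w_parent)
    ess <- pool_ess[parent]
    surv_p <- ifelse(ess, (1 - le)^el[[cl]], (1 - ln)^el[[cl]])
    keep <- stats::runif(n_ev) < surv_p
    if (!any(keep)) next
    rows[[cl]] <- data.frame(parent = parent[keep],
                             age_class = cl,
                             essential = ess[keep],
                             stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0) {
    empty_pairs <- data.frame(
      pair_id = character(), gene1 = character(), gene2 = character(),
      age_class = character(), essential = logical(), masked = logical(),
      ka_true = numeric(), w1 = numeric(), w2 = numeric(),
      w12 = numeric(), stringsAsFactors = FALSE)
    empty_genes <- data.frame(
      gene_id = character(), species = character(), essential = logical(),
      single_phenotype = logical(), expression_log2 = numeric(),
      protein_length = integer(), stringsAsFactors = FALSE)
    return(list(genes = empty_genes, pairs = empty_pairs,
                params = params))
  }
  np <- nrow(pairs)
  pairs$pair_id <- sprintf("P%05d", seq_len(np))
  pairs$gene1 <- paste0(pairs$pair_id, "a")
  pairs$gene2 <- paste0(pairs$pair_id, "b")
  expr <- pool_expr[pairs$parent]

  # divergence grows with age, falls with expression, with log-normal noise
  rate <- 2^(-params$expr_ka_slope * (expr - 10)) *
    stats::rlnorm(np, 0, 0.3)
  pairs$ka_true <- pmin(params$base_ka[pairs$age_class] * rate, 3)

  p_mask <- ifelse(pairs$essential,
                   exp(-params$masking_decay * pairs$ka_true), 0)
  pairs$masked <- stats::runif(np) < p_mask

  # single/double fitness truth: masked pairs are fully masked (clean
  # singles, sub-multiplicative double); unmasked essential pairs show the
  # defect on exactly one single, so the double equals the multiplicative
  # expectation and the single-knockdown call set is unambiguous
  w_def <- stats::runif(np, 0.2, 0.7)
  on_g1 <- stats::runif(np) < 0.5
  pairs$w1 <- ifelse(pairs$essential & !pairs$masked & on_g1, w_def, 1)
  pairs$w2 <- ifelse(pairs$essential & !pairs$masked & !on_g1, w_def, 1)
  pairs$w12 <- pairs$w1 * pairs$w2 *
    ifelse(pairs$masked, params$masking_strength, 1)

  jit <- function(k) stats::rnorm(k, 0, 0.2)
  genes <- data.frame(
    gene_id = c(pairs$gene1, pairs$gene2),
    species = "c_elegans",
    essential = rep(pairs$essential, 2),
    single_phenotype = c(pairs$w1 < 1, pairs$w2 < 1),
    expression_log2 = c(expr + jit(np), expr + jit(np)),
    protein_length = rep(200L + stats::rpois(np, 150), 2),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  pairs <- pairs[, c("pair_id", "gene1", "gene2", "age_class", "essential",
                     "masked", "ka_true", "w1", "w2", "w12")]
  rownames(pairs) <- NULL
  list(genes = genes, pairs = pairs, params = params)
}

#' Emit a tabular hit table for a simulated history
#'
#' Writes mutual hits for every true pair, with e-values from a fixed
#' monotone map of divergence (`log10 evalue = -150 (1 - divergence) +
#' jitter`, clamped to `[-180, -12]`), plus, for a configured fraction of
#' pairs, an injected third paralog hitting both members (so some pairs
#' exceed the isolation cutoff). The file round-trips through
#' [read_hit_table()].
#'
#' @param history Output of [simulate_history()].
#' @param path Output TSV path for the 12-column hit table.
#' @return Invisibly, a list with `path`, `protein_lengths` (named vector
#'   covering all genes in the table, including injected third paralogs)
#'   and `third_paralog_of` (named character vector, pair_id of affected
#'   pairs to third-gene id).
#' @export
emit_hit_table <- function(history, path) {
  pairs <- history$pairs
  genes <- history$genes
  params <- history$params
  set.seed(params$seed + 1L)
  np <- nrow(pairs)
  lens <- stats::setNames(genes$protein_length, genes$gene_id)

  d <- pmin(pairs$ka_true, 1)
  expo <- pmax(pmin(-150 * (1 - d) + stats::rnorm(np, 0, 2), -12), -180)
  ev <- 10^expo

  row_of <- function(q, s, e, lq, ls, dv) {
    data.frame(q = unname(q), s = unname(s),
               pident = round(pmax(100 * (1 - dv), 40), 1),
               length = unname(pmin(lq, ls)), mism = 0L, gapo = 0L,
               qs = 1L, qe = as.integer(round(0.9 * unname(lq))),
               ss = 1L, se = as.integer(round(0.9 * unname(ls))),
               evalue = unname(e), bits = round(-2 * log10(unname(e)), 1),
               stringsAsFactors = FALSE)
  }
  l1 <- lens[pairs$gene1]
  l2 <- lens[pairs$gene2]
  out <- rbind(row_of(pairs$gene1, pairs$gene2, ev, l1, l2, d),
               row_of(pairs$gene2, pairs$gene1, ev, l2, l1, d))

  third_of <- character(0)
  with_third <- which(stats::runif(np) < params$third_paralog_rate)
  if (length(with_third)) {
    u <- stats::runif(length(with_third), 0.4, 0.98)
    for (i in seq_along(with_third)) {
      k <- with_third[i]
      t_id <- paste0(pairs$pair_id[k], "t")
      t_len <- 200L + stats::rpois(1, 150)
      lens[t_id] <- t_len
      e_t <- 10^(expo[k] * u[i])
      tr <- rbind(
        row_of(pairs$gene1[k], t_id, e_t, lens[[pairs$gene1[k]]], t_len,
               d[k]),
        row_of(t_id, pairs$gene1[k], e_t, t_len, lens[[pairs$gene1[k]]],
               d[k]),
        row_of(pairs$gene2[k], t_id, e_t, lens[[pairs$gene2[k]]], t_len,
               d[k]),
        row_of(t_id, pairs$gene2[k], e_t, t_len, lens[[pairs$gene2[k]]],
               d[k]))
      out <- rbind(out, tr)
      third_of[pairs$pair_id[k]] <- t_id
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(path = path, protein_lengths = lens,
                 third_paralog_of = third_of))
}

.PQ_from_distance <- function(a, b) {
  Q <- (1 - exp(-2 * b)) / 2
  P <- (1 - Q - exp(-2 * a) * sqrt(1 - 2 * Q)) / 2
  c(P = max(P, 0), Q = max(Q, 0))
}

#' Simulate a codon-aligned sequence pair with target divergences
#'
#' Draws an ancestral sequence of sense codons and derives a partner by
#' per-site substitution: transition/transversion difference proportions per
#' degeneracy class are set by inverting the Kimura two-parameter distances
#' so that the realized nonsynonymous distance matches `ka` (nondegenerate
#' sites carry `ka`; twofold sites combine synonymous transitions with
#' nonsynonymous transversions; fourfold sites carry `ks`). Substitutions
#' that would create a stop codon are suppressed.
#'
#' @param n_codons Number of codons.
#' @param ka Target nonsynonymous distance.
#' @param ks Target synonymous distance.
#' @param tstv Transition/transversion distance ratio.
#' @return Character vector of two equal-length nucleotide strings.
#' @export
simulate_codon_pair <- function(n_codons, ka, ks, tstv = 2) {
  tab <- .degeneracy_table()
  gc <- Biostrings::GENETIC_CODE
  sense <- rownames(tab)
  aN <- ka * tstv / (1 + tstv)
  bN <- ka / (1 + tstv)
  aS <- ks * tstv / (1 + tstv)
  bS <- ks / (1 + tstv)
  pq <- list(`0` = .PQ_from_distance(aN, bN),
             `2` = .PQ_from_distance(aS, bN),
             `4` = .PQ_from_distance(aS, bS))
  s1 <- sample(sense, n_codons, replace = TRUE)
  s2 <- s1
  for (pos in 1:3) {
    cls <- as.character(tab[s1, pos])
    P <- vapply(pq, `[[`, 0, "P")[cls]
    Q <- vapply(pq, `[[`, 0, "Q")[cls]
    u <- stats::runif(n_codons)
    mut_ts <- u < P
    mut_tv <- !mut_ts & u < P + Q
    idx <- which(mut_ts | mut_tv)
    for (i in idx) {
      base <- substr(s2[i], pos, pos)
      new <- if (mut_ts[i]) {
        .TS_PARTNER[[base]]
      } else {
        sample(setdiff(.BASES, c(base, .TS_PARTNER[[base]])), 1)
      }
      cand <- s2[i]
      substr(cand, pos, pos) <- new
      if (gc[[cand]] != "*") s2[i] <- cand
    }
  }
  c(paste(s1, collapse = ""), paste(s2, collapse = ""))
}

#' Emit paired codon alignments for simulated pairs
#'
#' One alignment per pair, with the pair's true nonsynonymous divergence as
#' the simulation target (`ks` is set to three times `ka`, capped at 1.5).
#'
#' @param history Output of [simulate_history()].
#' @param path Output FASTA path; records are `pair_id|gene` in pair order.
#' @param n_codons Codons per alignment (defaults to the parameter value).
#' @return Invisibly, the named list of alignments (as in
#'   [read_codon_alignments()]).
#' @export
emit_codon_alignments <- function(history, path,
                                  n_codons = history$params$n_codons) {
  pairs <- history$pairs
  params <- history$params
  set.seed(params$seed + 2L)
  con <- file(path, "w")
  on.exit(close(con))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    aln <- simulate_codon_pair(n_codons, pairs$ka_true[i],
                               min(3 * pairs$ka_true[i], 1.5),
                               params$tstv)
    writeLines(c(paste0(">", pairs$pair_id[i], "|", pairs$gene1[i]), aln[1],
                 paste0(">", pairs$pair_id[i], "|", pairs$gene2[i]), aln[2]),
               con)
    out[[i]] <- aln
    names(out)[i] <- pairs$pair_id[i]
  }
  invisible(out)
}

#' Reference species taxonomy used by the generator
#'
#' A rooted species tree for the six species the generator emits, with the
#' age classes as internal node labels.
#'
#' @return An `ape::phylo` taxonomy.
#' @export
default_taxonomy <- function() {
  ape::read.tree(text = paste0(
    "(((c_elegans,c_briggsae)Caenorhabditis,",
    "(h_sapiens,d_melanogaster)Deuterostomia_split)Bilateria,",
    "(s_cerevisiae,a_thaliana)Outgroups)Eukaryota;"))
}

.pair_tree_text <- function(pair_id, g1, g2, age, bs) {
  b <- function() sample(bs, 1)
  ortho <- function(g, sp) paste0(g, "_", sp)
  switch(age,
    Celegans = sprintf("((%s:1,%s:1)%d:1,%s:2)%d;",
                       g1, g2, b(), ortho(pair_id, "cb"), b()),
    Caenorhabditis = sprintf("((%s:1,%s:1)%d:1,(%s:1,%s:1)%d:1)%d;",
                             g1, ortho(g1, "cb"), b(),
                             g2, ortho(g2, "cb"), b(), b()),
    Bilateria = sprintf("(((%s:1,%s:1)%d:1,(%s:1,%s:1)%d:1)%d:1,%s:3)%d;",
                        g1, ortho(g1, "hs"), b(),
                        g2, ortho(g2, "hs"), b(), b(),
                        ortho(pair_id, "sc"), b()),
    Eukaryota = sprintf("((%s:1,%s:1)%d:1,(%s:1,%s:1)%d:1)%d;",
                        g1, ortho(g1, "sc"), b(),
                        g2, ortho(g2, "sc"), b(), b()),
    stop("unknown age class '", age, "'"))
}

.pair_tree_species <- function(pair_id, g1, g2, age) {
  ortho <- function(g, sp) paste0(g, "_", sp)
  switch(age,
    Celegans = stats::setNames(
      c("c_elegans", "c_elegans", "c_briggsae"),
      c(g1, g2, ortho(pair_id, "cb"))),
    Caenorhabditis = stats::setNames(
      c("c_elegans", "c_briggsae", "c_elegans", "c_briggsae"),
      c(g1, ortho(g1, "cb"), g2, ortho(g2, "cb"))),
    Bilateria = stats::setNames(
      c("c_elegans", "h_sapiens", "c_elegans", "h_sapiens", "s_cerevisiae"),
      c(g1, ortho(g1, "hs"), g2, ortho(g2, "hs"), ortho(pair_id, "sc"))),
    Eukaryota = stats::setNames(
      c("c_elegans", "s_cerevisiae", "c_elegans", "s_cerevisiae"),
      c(g1, ortho(g1, "sc"), g2, ortho(g2, "sc"))))
}

#' Emit bootstrap-annotated gene trees for simulated pairs
#'
#' Builds, for each pair and each of `n_releases` releases, a small rooted
#' gene tree whose duplication node sits at the taxonomic level of the
#' pair's true age. For confident fixtures bootstraps are drawn high
#' (85-100); a configurable fraction of pairs instead receives low
#' bootstraps (placed in release files all the same way, but since the
#' releases still agree topologically, low-support fixtures are only
#' `Unknown` when `n_releases = 1`).
#'
#' @param history Output of [simulate_history()].
#' @param dir Optional directory; when given, writes
#'   `release_<i>.nwk` (one tree per line, pair order) and
#'   `species_map.tsv` there.
#' @param n_releases Number of releases to emit (most recent last).
#' @param low_support_rate Fraction of pairs drawn with bootstraps 30-69.
#' @return List with `trees` (list of `n_releases` lists of `phylo`),
#'   `species_map` (named vector) and `taxonomy`.
#' @export
emit_gene_trees <- function(history, dir = NULL, n_releases = 3,
                            low_support_rate = 0) {
  pairs <- history$pairs
  params <- history$params
  set.seed(params$seed + 3L)
  np <- nrow(pairs)
  low <- stats::runif(np) < low_support_rate
  species_map <- character(0)
  releases <- vector("list", n_releases)
  for (r in seq_len(n_releases)) releases[[r]] <- vector("list", np)
  texts <- matrix("", nrow = np, ncol = n_releases)
  for (i in seq_len(np)) {
    bs <- if (low[i]) 30:69 else 85:100
    sm <- .pair_tree_species(pairs$pair_id[i], pairs$gene1[i],
                             pairs$gene2[i], pairs$age_class[i])
    species_map <- c(species_map, sm)
    for (r in seq_len(n_releases)) {
      txt <- .pair_tree_text(pairs$pair_id[i], pairs$gene1[i],
                             pairs$gene2[i], pairs$age_class[i], bs)
      texts[i, r] <- txt
      releases[[r]][[i]] <- ape::read.tree(text = txt)
    }
  }
  for (r in seq_len(n_releases)) names(releases[[r]]) <- pairs$pair_id
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_len(n_releases)) {
      writeLines(texts[, r], file.path(dir, sprintf("release_%d.nwk", r)))
    }
    utils::write.table(
      data.frame(gene_id = names(species_map), species = species_map),
      file.path(dir, "species_map.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(trees = releases, species_map = species_map,
       taxonomy = default_taxonomy())
}

.SCREEN_MEASURES <- c("brood", "embryonic_viability",
                      "postembryonic_viability", "morphology_normal")
.MEASURE_SCALE <- c(brood = 250, embryonic_viability = 100,
                    postembryonic_viability = 100, morphology_normal = 100)

#' Emit replicate-level screen tables for simulated pairs
#'
#' Produces the quantitative and qualitative observation tables of a single
#' plus double knockdown screen. Every condition (each single gene, each
#' pair's double, and the control) receives `replicate_count` replicate
#' values per quantitative measure, drawn around the condition's true
#' fitness times the measure scale with coefficient of variation
#' `noise_cv`; each pair's defect is expressed in one randomly chosen
#' measure. Control wells (`n_controls` of them) are drawn at fitness 1.
#' Qualitative penetrant observations are generated consistently with the
#' quantitative severities (conditions with fitness below 0.9 receive a
#' phenotype code whose severity and stage escalate as fitness drops).
#'
#' @param history Output of [simulate_history()].
#' @param quant_path,qual_path Optional TSV output paths.
#' @return List with `quantitative` (condition_id, condition_type,
#'   replicate, measure, value), `qualitative` (condition_id, replicate,
#'   generation, phenotype_code, penetrance, stage) and `defect_measure`
#'   (named by pair_id).
#' @export
emit_screen_tables <- function(history, quant_path = NULL,
                               qual_path = NULL) {
  pairs <- history$pairs
  params <- history$params
  set.seed(params$seed + 4L)
  nrep <- params$replicate_count
  cv <- params$noise_cv
  np <- nrow(pairs)

  defect_measure <- stats::setNames(
    sample(.SCREEN_MEASURES, np, replace = TRUE), pairs$pair_id)

  cond <- data.frame(
    condition_id = c(pairs$gene1, pairs$gene2, pairs$pair_id),
    condition_type = rep(c("single", "single", "double"), each = np),
    w = c(pairs$w1, pairs$w2, pairs$w12),
    defect_measure = rep(defect_measure, 3),
    stringsAsFactors = FALSE)

  draw <- function(mu, n) {
    v <- stats::rnorm(n, mu, cv * mu)
    pmax(v, 0)
  }
  quant <- do.call(rbind, lapply(.SCREEN_MEASURES, function(ms) {
    w_ms <- ifelse(cond$defect_measure == ms, cond$w, 1)
    mu <- w_ms * .MEASURE_SCALE[[ms]]
    data.frame(
      condition_id = rep(cond$condition_id, each = nrep),
      condition_type = rep(cond$condition_type, each = nrep),
      replicate = rep(seq_len(nrep), nrow(cond)),
      measure = ms,
      value = draw(rep(mu, each = nrep), nrep * nrow(cond)),
      stringsAsFactors = FALSE)
  }))
  ctrl <- do.call(rbind, lapply(.SCREEN_MEASURES, function(ms) {
    data.frame(
      condition_id = "control", condition_type = "control",
      replicate = seq_len(params$n_controls), measure = ms,
      value = draw(rep(.MEASURE_SCALE[[ms]], params$n_controls),
                   params$n_controls),
      stringsAsFactors = FALSE)
  }))
  quant <- rbind(quant, ctrl)
  rownames(quant) <- NULL

  # qualitative observations mirror quantitative severity
  qual_rows <- cond[cond$w < 0.9, , drop = FALSE]
  qual <- if (nrow(qual_rows)) {
    code <- ifelse(qual_rows$w < 0.3, "Lvl",
                   ifelse(qual_rows$w < 0.6, "Lvl", "Gro"))
    stage <- ifelse(qual_rows$w < 0.3, "L1", "L3")
    do.call(rbind, lapply(seq_len(nrow(qual_rows)), function(i) {
      pen <- pmin(pmax(stats::rnorm(nrep, 1 - qual_rows$w[i],
                                    0.05), 0), 1)
      data.frame(condition_id = qual_rows$condition_id[i],
                 replicate = seq_len(nrep), generation = "F1",
                 phenotype_code = code[i], penetrance = pen,
                 stage = stage[i], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(condition_id = character(), replicate = integer(),
               generation = character(), phenotype_code = character(),
               penetrance = numeric(), stage = character(),
               stringsAsFactors = FALSE)
  }

  if (!is.null(quant_path)) {
    utils::write.table(quant, quant_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(qual_path)) {
    utils::write.table(qual, qual_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(quantitative = quant, qualitative = qual,
       defect_measure = defect_measure)
}
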