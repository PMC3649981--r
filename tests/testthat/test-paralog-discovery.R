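test_that("hit tables parse, drop self-hits and compute coverage", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "A\tB\t95.0\t90\t4\t0\t1\t90\t1\t90\t1e-50\t180",
    "B\tA\t95.0\t90\t4\t0\t1\t90\t1\t90\t1e-50\t180",
    "A\tA\t100.0\t100\t0\t0\t1\t100\t1\t100\t0\t200",
    "A\tC\t40.0\t50\t30\t0\t1\t50\t10\t59\t1e-5\t60",
    "C\tA\t40.0\t50\t30\t0\t10\t59\t1\t50\t1e-5\t60")
  writeLines(rows, tmp)
  lens <- c(A = 100, B = 100, C = 120)
  hits <- read_hit_table(tmp, lens)
  # self row dropped: 4 of 5 rows survive
  expect_equal(nrow(hits), 4L)
  expect_false(any(hits$query_id == hits$subject_id))
  ab <- hits[hits$query_id == "A" & hits$subject_id == "B", ]
  expect_equal(ab$qcov, 0.9)
  expect_equal(ab$scov, 0.9)
  # empty file gives an empty frame
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(read_hit_table(empty, lens)), 0L)
  # missing protein length is reported by gene id
  expect_error(read_hit_table(tmp, lens[c("A", "B")]), "C")
})

test_that("multiple HSPs per directed pair reduce to the best one", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "A\tB\t90\t50\t5\t0\t1\t50\t1\t50\t1e-20\t100",
    "A\tB\t90\t80\t8\t0\t1\t80\t1\t80\t1e-40\t150"), tmp)
  hits <- read_hit_table(tmp, c(A = 100, B = 100))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$evalue, 1e-40)
  expect_equal(hits$qcov, 0.8)
})

test_that("reciprocal best pairs follow the mutual-best definition", {
  # two genes hitting only each other -> one pair
  h <- make_hits(c("A", "B"), c("B", "A"), c(1e-50, 1e-50))
  got <- reciprocal_best_pairs(h)
  expect_equal(got$gene1, "A")
  expect_equal(got$gene2, "B")
  expect_equal(got$pair_evalue, 1e-50)

  # reciprocity violated: A's best is B but B's best is C
  h2 <- make_hits(c("A", "B", "B", "C"), c("B", "C", "A", "B"),
                  c(1e-50, 1e-60, 1e-50, 1e-60))
  got2 <- reciprocal_best_pairs(h2)
  expect_false("A" %in% c(got2$gene1, got2$gene2))
  expect_true(all(got2$gene1 == "B" & got2$gene2 == "C"))

  # coverage rule: both directions must span at least 60% of each protein
  h3 <- make_hits(c("A", "B"), c("B", "A"), c(1e-50, 1e-50),
                  qcov = c(0.9, 0.5), scov = c(0.9, 0.9))
  expect_equal(nrow(reciprocal_best_pairs(h3)), 0L)
  # e-value threshold is strict
  h4 <- make_hits(c("A", "B"), c("B", "A"), c(1e-9, 1e-10))
  expect_equal(nrow(reciprocal_best_pairs(h4)), 0L)
})

test_that("reciprocal_best_pairs equals exhaustive search on random tables", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    hits <- random_hit_table(n)
    if (nrow(hits) == 0) next
    got <- reciprocal_best_pairs(hits, max_evalue = 1e-9, min_cov = 0.6)
    want <- rbh_oracle(hits, max_evalue = 1e-9, min_cov = 0.6)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    # mutual-best pairs are disjoint in genes
    expect_false(anyDuplicated(c(got$gene1, got$gene2)) > 0)
  }
})

test_that("single-copy classification uses the 0.01 threshold", {
  hits <- make_hits(c("A", "C"), c("B", "D"), c(0.5, 1e-3))
  genes <- c("A", "B", "C", "D", "E")
  sc <- classify_single_copy(hits, genes)
  # a hit at 0.5 does not disqualify; 1e-3 does (both directions count)
  expect_setequal(sc, c("A", "B", "E"))
})

test_that("isolation value reproduces the worked examples", {
  # pair at 1e-100 with closest shared hit at 1e-83 -> 0.83 exactly
  hits <- make_hits(
    c("A", "B", "A", "B", "C", "C"),
    c("B", "A", "C", "C", "A", "B"),
    c(1e-100, 1e-100, 1e-83, 1e-90, 1e-83, 1e-90))
  expect_identical(isolation_value("A", "B", hits), 0.83)

  # pair at 1e-15 with shared hit max 3.5e-13 -> 0.830 (3 decimals)
  hits2 <- make_hits(
    c("A", "B", "A", "B"),
    c("B", "A", "C", "C"),
    c(1e-15, 1e-15, 3.5e-13, 1e-14))
  expect_equal(round(isolation_value("A", "B", hits2), 3), 0.830)

  # no shared hit -> 0
  hits3 <- make_hits(c("A", "B"), c("B", "A"), c(1e-50, 1e-50))
  expect_identical(isolation_value("A", "B", hits3), 0)

  # shared-hit candidates must clear the 0.01 threshold
  hits4 <- make_hits(c("A", "B", "A", "B"), c("B", "A", "C", "C"),
                     c(1e-50, 1e-50, 0.5, 0.02))
  expect_identical(isolation_value("A", "B", hits4), 0)

  # pair absent from the table is an error
  expect_error(isolation_value("A", "Z", hits3), "Z")
})

test_that("isolation is clamped to [0,1] and monotone in the shared hit", {
  base <- function(ev_shared) {
    h <- make_hits(
      c("A", "B", "A", "B"),
      c("B", "A", "C", "C"),
      c(1e-40, 1e-40, ev_shared, ev_shared))
    isolation_value("A", "B", h)
  }
  # a shared hit more significant than the pair hit clamps at 1
  expect_identical(base(1e-60), 1)
  # more significant shared hit never decreases isolation
  evs <- 10^seq(-3, -39, by = -4)
  vals <- vapply(evs, base, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  # e-value underflow is clamped, keeping the value finite
  h0 <- make_hits(c("A", "B", "A", "B"), c("B", "A", "C", "C"),
                  c(0, 0, 1e-90, 1e-90))
  expect_equal(isolation_value("A", "B", h0), 0.5)
})

test_that("isolation filter keeps 0.83 and removes 0.84", {
  pairs <- data.frame(gene1 = c("a", "c", "e"), gene2 = c("b", "d", "f"),
                      isolation = c(0.83, 0.84, 0),
                      stringsAsFactors = FALSE)
  kept <- filter_isolated_pairs(pairs)
  expect_setequal(kept$gene1, c("a", "e"))
  # cutoff 1.0 is the identity
  expect_equal(nrow(filter_isolated_pairs(pairs, cutoff = 1.0)), 3L)
  # brute-force comparison on a random set
  set.seed(7)
  pr <- data.frame(gene1 = letters[1:10], gene2 = LETTERS[1:10],
                   isolation = stats::runif(10), stringsAsFactors = FALSE)
  expect_equal(filter_isolated_pairs(pr, 0.5),
               pr[pr$isolation <= 0.5, ])
})

test_that("probe target classes follow the identity/span thresholds", {
  seg <- data.frame(
    probe_id = c("p1", "p2", "p3"),
    gene_id = c("g1", "g2", "g3"),
    identity = c(0.96, 0.85, 0.70),
    span_bp = c(120L, 250L, 500L),
    stringsAsFactors = FALSE)
  cls <- probe_target_classes(seg)
  expect_equal(cls$class[cls$probe_id == "p1"], "primary")
  expect_equal(cls$class[cls$probe_id == "p2"], "secondary")
  expect_equal(cls$class[cls$probe_id == "p3"], "none")
  # a long high-identity segment is primary, not secondary
  seg2 <- data.frame(probe_id = "p", gene_id = "g", identity = 0.97,
                     span_bp = 300L, stringsAsFactors = FALSE)
  expect_equal(probe_target_classes(seg2)$class, "primary")
})

test_that("uniquely targetable pairs require clean probes on both sides", {
  pairs <- data.frame(gene1 = c("g1", "g3"), gene2 = c("g2", "g4"),
                      stringsAsFactors = FALSE)
  seg <- data.frame(
    probe_id = c("p1", "p2", "p3", "p3", "p4"),
    gene_id = c("g1", "g2", "g3", "g4", "g4"),
    identity = c(0.99, 0.99, 0.99, 0.85, 0.99),
    span_bp = c(300L, 300L, 300L, 300L, 300L),
    stringsAsFactors = FALSE)
  # p3 targets g3 primarily but also hits g4 at 0.85/300bp (secondary):
  # g3 has no clean probe, so the (g3,g4) pair is removed
  kept <- uniquely_targetable_pairs(pairs, seg)
  expect_equal(kept$gene1, "g1")

  # exhaustive per-probe evaluation on a small fixture
  set.seed(11)
  genes <- sprintf("g%d", 1:16)
  pairs8 <- data.frame(gene1 = genes[seq(1, 15, 2)],
                       gene2 = genes[seq(2, 16, 2)],
                       stringsAsFactors = FALSE)
  seg8 <- data.frame(
    probe_id = paste0("pr", seq_along(genes)),
    gene_id = genes,
    identity = stats::runif(16, 0.9, 1),
    span_bp = sample(c(90L, 150L, 300L), 16, replace = TRUE),
    stringsAsFactors = FALSE)
  # add some cross-hybridising segments
  extra <- data.frame(
    probe_id = paste0("pr", c(1, 4, 9)),
    gene_id = genes[c(2, 3, 10)],
    identity = c(0.85, 0.70, 0.92),
    span_bp = c(250L, 400L, 260L),
    stringsAsFactors = FALSE)
  seg_all <- rbind(seg8, extra)
  got <- uniquely_targetable_pairs(pairs8, seg_all)
  cls <- probe_target_classes(seg_all)
  clean <- vapply(genes, function(g) {
    probes <- unique(cls$probe_id[cls$gene_id == g &
                                    cls$class == "primary"])
    any(vapply(probes, function(p) {
      sub <- cls[cls$probe_id == p, ]
      sum(sub$class == "primary") == 1 && !any(sub$class == "secondary")
    }, logical(1)))
  }, logical(1))
  want <- pairs8[clean[pairs8$gene1] & clean[pairs8$gene2], ]
  expect_equal(got, want)
})
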