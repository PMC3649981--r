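# Small fixed fixtures: gene trees over the six generator species, with the
# default taxonomy.

tax <- default_taxonomy()

sm <- c(ce1 = "c_elegans", ce2 = "c_elegans", ce3 = "c_elegans",
        cb1 = "c_briggsae", cb2 = "c_briggsae",
        hs1 = "h_sapiens", dm1 = "d_melanogaster",
        sc1 = "s_cerevisiae", at1 = "a_thaliana")

test_that("duplication node is the lowest common ancestor", {
  tr <- ape::read.tree(text = "((ce1:1,ce2:1)90:1,(cb1:1,hs1:1)90:1)95;")
  # siblings map to their parent; cross-clade pairs map to the root
  ntip <- length(tr$tip.label)
  expect_equal(duplication_node(tr, "ce1", "ce2"), ntip + 2L)
  expect_equal(duplication_node(tr, "ce1", "hs1"), ntip + 1L)
  expect_error(duplication_node(tr, "ce1", "zz"), "zz")
  # random trees against the path-intersection oracle
  set.seed(41)
  for (i in 1:10) {
    rt <- ape::rtree(12)
    tips <- sample(rt$tip.label, 2)
    expect_equal(duplication_node(rt, tips[1], tips[2]),
                 lca_oracle(rt, tips[1], tips[2]))
  }
})

test_that("node age class maps descendant species onto the taxonomy", {
  tr <- ape::read.tree(
    text = "(((ce1:1,ce2:1)90:1,cb1:2)90:1,(hs1:2,sc1:2)90:1)95;")
  ntip <- length(tr$tip.label)
  # clade of only C. elegans genes
  n_ce <- duplication_node(tr, "ce1", "ce2")
  expect_equal(node_age_class(n_ce, tr, sm, tax), "Celegans")
  # spanning elegans and briggsae
  n_cae <- duplication_node(tr, "ce1", "cb1")
  expect_equal(node_age_class(n_cae, tr, sm, tax), "Caenorhabditis")
  # worm plus human at the root, with yeast: Eukaryota; worm plus human
  # alone: Bilateria
  tr2 <- ape::read.tree(text = "((ce1:1,hs1:1)90:1,cb1:2)95;")
  expect_equal(node_age_class(duplication_node(tr2, "ce1", "hs1"),
                              tr2, sm, tax), "Bilateria")
  expect_equal(node_age_class(duplication_node(tr, "ce1", "sc1"),
                              tr, sm, tax), "Eukaryota")
  # species missing from the taxonomy error out
  sm_bad <- c(sm, xx = "x_species")
  tr3 <- ape::read.tree(text = "((ce1:1,xx:1)90:1,cb1:2)95;")
  expect_error(node_age_class(duplication_node(tr3, "ce1", "xx"),
                              tr3, sm_bad, tax), "x_species")
})

test_that("age classes are monotone under clade enlargement", {
  # walking the duplication node rootwards never decreases the class
  tr <- ape::read.tree(text = paste0(
    "((((ce1:1,ce2:1)90:1,cb1:2)90:1,hs1:3)90:1,sc1:4)95;"))
  classes <- age_classes()
  nodes <- c(duplication_node(tr, "ce1", "ce2"),
             duplication_node(tr, "ce1", "cb1"),
             duplication_node(tr, "ce1", "hs1"),
             duplication_node(tr, "ce1", "sc1"))
  ranks <- match(vapply(nodes, node_age_class, "", tree = tr,
                        species_map = sm, taxonomy = tax), classes)
  expect_true(all(diff(ranks) >= 0))
})

test_that("speciation nodes are detected by species overlap", {
  tr <- ape::read.tree(text = "((ce1:1,cb1:1)90:1,(ce2:1,cb2:1)90:1)50;")
  ntip <- length(tr$tip.label)
  expect_true(is_speciation_node(ntip + 2L, tr, sm))   # (ce1,cb1)
  expect_false(is_speciation_node(ntip + 1L, tr, sm))  # root duplication
})

test_that("strong support needs bootstraps or complete speciation nodes", {
  # all path bootstraps high
  t_hi <- ape::read.tree(text = "((ce1:1,ce2:1)90:1,cb1:2)95;")
  expect_true(support_confident(t_hi, "ce1", "ce2", sm, tax))
  # ancestor bootstrap below threshold
  t_lo <- ape::read.tree(text = "((ce1:1,ce2:1)60:1,cb1:2)95;")
  expect_false(support_confident(t_lo, "ce1", "ce2", sm, tax))
  # a weak path node that is a complete speciation node is exempt:
  # (ce1,cb1) at bootstrap 50 spans the full Caenorhabditis species set
  t_mix <- ape::read.tree(
    text = "((ce1:1,cb1:1)50:1,(ce2:1,cb2:1)90:1)85;")
  expect_true(support_confident(t_mix, "ce1", "ce2", sm, tax))
  # the same topology with the weak node missing a species is not exempt
  sm2 <- c(sm, cr1 = "c_remanei")
  tax2 <- ape::read.tree(text = paste0(
    "((((c_elegans,c_briggsae)Inner,c_remanei)Caenorhabditis,",
    "(h_sapiens,d_melanogaster)X)Bilateria,",
    "(s_cerevisiae,a_thaliana)Y)Eukaryota;"))
  t_inc <- ape::read.tree(
    text = "((ce1:1,cr1:1)50:1,(ce2:1,cb2:1)90:1)85;")
  expect_false(support_confident(t_inc, "ce1", "ce2", sm2, tax2))
  # missing bootstrap on the ancestor fails
  t_na <- ape::read.tree(text = "((ce1:1,ce2:1):1,cb1:2)95;")
  expect_false(support_confident(t_na, "ce1", "ce2", sm, tax))
})

test_that("pair dating follows release agreement and strong support", {
  t_cae <- ape::read.tree(
    text = "((ce1:1,cb1:1)40:1,(ce2:1,cb2:1)40:1)40;")  # Caenorhabditis
  t_bil <- ape::read.tree(
    text = "(((ce1:1,hs1:1)40:1,ce2:1)40:1,cb1:3)40;")  # Bilateria
  # two of three releases agree despite weak bootstraps
  d <- date_pair(list(t_cae, t_cae, t_bil), "ce1", "ce2", sm, tax)
  expect_equal(d$age_class, "Caenorhabditis")
  expect_true(d$confident)
  expect_equal(d$basis, "multi-release-agreement")
  # a single fully supported release
  t_strong <- ape::read.tree(
    text = "((ce1:1,cb1:1)90:1,(ce2:1,cb2:1)90:1)90;")
  d2 <- date_pair(list(t_strong), "ce1", "ce2", sm, tax)
  expect_equal(d2$age_class, "Caenorhabditis")
  expect_equal(d2$basis, "strong-support")
  # a single weak release is Unknown
  d3 <- date_pair(list(t_cae), "ce1", "ce2", sm, tax)
  expect_equal(d3$age_class, "Unknown")
  expect_false(d3$confident)
})

test_that("split families date to Eukaryota only with the deep taxa", {
  fams <- data.frame(
    gene_id = c("ce1", "hs1", "dm1", "sc1", "ce2", "hs2", "dm2", "at2"),
    family_id = c("F1", "F1", "F1", "F1", "F2", "F2", "F2", "F2"),
    stringsAsFactors = FALSE)
  sm_f <- c(sm, hs2 = "h_sapiens", dm2 = "d_melanogaster",
            at2 = "a_thaliana")
  d <- date_pair(list(), "ce1", "ce2", sm_f, tax, families = fams)
  expect_equal(d$age_class, "Eukaryota")
  expect_equal(d$basis, "family-split-rule")
  # one family lacking Drosophila genes -> Unknown
  fams2 <- fams[fams$gene_id != "dm2", ]
  d2 <- date_pair(list(), "ce1", "ce2", sm_f, tax, families = fams2)
  expect_equal(d2$age_class, "Unknown")
})

test_that("ortholog inference restricts to supported one-to-one speciations", {
  # two-leaf tree, one gene per species
  t2 <- ape::read.tree(text = "(ce1:1,cb1:1)90;")
  o <- infer_orthologs(t2, sm, "c_elegans", "c_briggsae")
  expect_equal(o$geneA, "ce1")
  expect_equal(o$geneB, "cb1")
  # duplication at the root: two ortholog pairs, paired within clades
  t4 <- ape::read.tree(text = "((ce1:1,cb1:1)90:1,(ce2:1,cb2:1)90:1)50;")
  o4 <- infer_orthologs(t4, sm, "c_elegans", "c_briggsae")
  expect_equal(nrow(o4), 2L)
  expect_setequal(paste(o4$geneA, o4$geneB),
                  c("ce1 cb1", "ce2 cb2"))
  # weak support drops a pair
  t4b <- ape::read.tree(text = "((ce1:1,cb1:1)50:1,(ce2:1,cb2:1)90:1)50;")
  o4b <- infer_orthologs(t4b, sm, "c_elegans", "c_briggsae")
  expect_equal(paste(o4b$geneA, o4b$geneB), "ce2 cb2")
  # exhaustive scan oracle on a larger synthetic tree
  t10 <- ape::read.tree(text = paste0(
    "(((ce1:1,cb1:1)90:1,(ce2:1,cb2:1)80:1)70:1,",
    "((ce3:1,cb3:1)95:1,(ce4:1,(cb4:1,cb5:1)88:1)92:1)75:1)60;"))
  sm10 <- c(ce1 = "c_elegans", ce2 = "c_elegans", ce3 = "c_elegans",
            ce4 = "c_elegans", cb1 = "c_briggsae", cb2 = "c_briggsae",
            cb3 = "c_briggsae", cb4 = "c_briggsae", cb5 = "c_briggsae")
  got <- infer_orthologs(t10, sm10, "c_elegans", "c_briggsae")
  # oracle: candidate cross pairs at supported speciation LCAs, then
  # one-to-one restriction
  tipsA <- names(sm10)[sm10 == "c_elegans"]
  tipsB <- names(sm10)[sm10 == "c_briggsae"]
  cand <- NULL
  for (a in tipsA) {
    for (b in tipsB) {
      lca <- lca_oracle(t10, a, b)
      kids <- t10$edge[t10$edge[, 1] == lca, 2]
      spt <- function(nd) {
        if (nd <= length(t10$tip.label)) {
          sm10[t10$tip.label[nd]]
        } else {
          idx <- phangorn::Descendants(t10, nd, "tips")[[1]]
          unique(sm10[t10$tip.label[idx]])
        }
      }
      sets <- lapply(kids, spt)
      if (length(unlist(sets)) != length(unique(unlist(sets)))) next
      bs <- as.numeric(t10$node.label[lca - length(t10$tip.label)])
      if (is.na(bs) || bs < 70) next
      cand <- rbind(cand, data.frame(geneA = a, geneB = b))
    }
  }
  keep <- !(cand$geneA %in% cand$geneA[duplicated(cand$geneA)]) &
    !(cand$geneB %in% cand$geneB[duplicated(cand$geneB)])
  want <- cand[keep, ]
  expect_setequal(paste(got$geneA, got$geneB),
                  paste(want$geneA, want$geneB))
})

test_that("unrooted input trees are midpoint-rooted with a warning", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(ce1:1,ce2:2,cb1:3);", tmp)
  expect_warning(tr <- read_gene_tree(tmp), "midpoint")
  expect_true(ape::is.rooted(tr))
})
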