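# Duplication-age dating from bootstrap-annotated gene trees: locate the
# duplication node for a pair, map its descendant species onto a species
# taxonomy, apply bootstrap/speciation confidence rules across releases,
# and infer cross-species orthologs from speciation nodes.

#' Ordered duplication age classes
#'
#' Age classes from youngest to oldest: a duplication in the focal lineage
#' after the last speciation (`Celegans`), in the Caenorhabditis ancestor,
#' in the Bilaterian ancestor, or in the eukaryote (or earlier) ancestor.
#'
#' @return Character vector of the four dated classes in increasing age.
#' @export
age_classes <- function() {
  c("Celegans", "Caenorhabditis", "Bilateria", "Eukaryota")
}

#' Read a gene tree from Newick
#'
#' Internal node labels are interpreted as bootstrap percentages in
#' `[0, 100]` (blank = missing). Unrooted trees are midpoint-rooted with a
#' warning, since locating a duplication node requires a rooted tree.
#'
#' @param path Newick file (may contain one tree).
#' @return An `ape::phylo` tree.
#' @export
read_gene_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (!ape::is.rooted(tree)) {
    warning("input tree is unrooted; midpoint-rooting it", call. = FALSE)
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Read a gene-to-species map
#'
#' @param path TSV with columns `gene_id` and `species`.
#' @return Named character vector mapping gene id to species.
#' @export
read_species_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         stringsAsFactors = FALSE)
  stats::setNames(d$species, d$gene_id)
}

.node_bootstrap <- function(tree, node) {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) return(NA_real_)
  v <- suppressWarnings(as.numeric(lab[node - ntip]))
  if (length(v) == 0) NA_real_ else v
}

.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  idx <- phangorn::Descendants(tree, node, type = "tips")[[1]]
  tree$tip.label[idx]
}

.species_under <- function(tree, node, species_map) {
  tips <- .tips_under(tree, node)
  miss <- setdiff(tips, names(species_map))
  if (length(miss)) {
    stop("gene '", miss[1], "' missing from the species map", call. = FALSE)
  }
  unique(unname(species_map[tips]))
}

.node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

.node_parent <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(p) == 0) NA_integer_ else p
}

#' Duplication node of a gene pair
#'
#' The lowest common ancestor of the two genes in a rooted gene tree.
#'
#' @param tree Rooted `phylo` gene tree.
#' @param gene1,gene2 Tip labels.
#' @return Internal node id.
#' @export
duplication_node <- function(tree, gene1, gene2) {
  miss <- setdiff(c(gene1, gene2), tree$tip.label)
  if (length(miss)) {
    stop("gene '", miss[1], "' is not a leaf of the tree", call. = FALSE)
  }
  ape::getMRCA(tree, c(gene1, gene2))
}

# Taxonomy node whose clade is the LCA of a species set; for a single
# species this is its tip.
.taxonomy_lca <- function(taxonomy, species) {
  miss <- setdiff(species, taxonomy$tip.label)
  if (length(miss)) {
    stop("species '", miss[1], "' not present in the taxonomy",
         call. = FALSE)
  }
  if (length(species) == 1) {
    return(which(taxonomy$tip.label == species))
  }
  ape::getMRCA(taxonomy, species)
}

# Nearest ancestor (or self) of a taxonomy node whose label is a recognised
# age class.
.taxon_age_label <- function(taxonomy, node) {
  ntip <- length(taxonomy$tip.label)
  classes <- age_classes()
  cur <- node
  while (!is.na(cur)) {
    if (cur > ntip) {
      lab <- taxonomy$node.label[cur - ntip]
      if (!is.null(lab) && lab %in% classes) return(lab)
    }
    cur <- .node_parent(taxonomy, cur)
  }
  stop("no age-class label found on the taxonomy path; taxonomy must label ",
       "nodes with ", paste(classes, collapse = ", "), call. = FALSE)
}

#' Age class of a gene-tree node
#'
#' The taxonomic level of the node: the age-class label of the lowest
#' common ancestor, in the species taxonomy, of all species found among the
#' node's descendant leaves. A clade containing only the focal species is
#' the youngest class (`"Celegans"`).
#'
#' @param node Internal node id of `tree`.
#' @param tree Rooted gene tree.
#' @param species_map Named character vector, gene id to species.
#' @param taxonomy Rooted species tree (`phylo`) whose tips are species and
#'   whose internal node labels include the age classes of [age_classes()].
#' @param focal_species Species whose lineage defines the youngest class.
#' @return One of [age_classes()].
#' @export
node_age_class <- function(node, tree, species_map, taxonomy,
                           focal_species = "c_elegans") {
  sp <- .species_under(tree, node, species_map)
  if (length(sp) == 1 && sp == focal_species) return("Celegans")
  .taxon_age_label(taxonomy, .taxonomy_lca(taxonomy, sp))
}

#' Is a gene-tree node a speciation node?
#'
#' Species-overlap criterion: the node is a speciation node when its child
#' clades contain pairwise disjoint species sets; any shared species implies
#' a duplication.
#'
#' @inheritParams node_age_class
#' @return Logical.
#' @export
is_speciation_node <- function(node, tree, species_map) {
  kids <- .node_children(tree, node)
  if (length(kids) < 2) return(FALSE)
  sets <- lapply(kids, .species_under, tree = tree,
                 species_map = species_map)
  tot <- unlist(sets)
  length(tot) == length(unique(tot))
}

# A speciation node "at which no genes have been lost": its descendant
# species set equals the full species set expected under its taxon in the
# taxonomy.
.complete_speciation <- function(node, tree, species_map, taxonomy) {
  if (!is_speciation_node(node, tree, species_map)) return(FALSE)
  sp <- .species_under(tree, node, species_map)
  tax_node <- .taxonomy_lca(taxonomy, sp)
  expected <- .tips_under(taxonomy, tax_node)
  setequal(sp, expected)
}

#' Is a pair's duplication date strongly supported?
#'
#' The date is strongly supported when the bootstrap of the pair's common
#' ancestor node is at least `min_bootstrap`, and every internal node on the
#' paths from both genes back to that ancestor either has bootstrap at least
#' `min_bootstrap` or is a speciation node at which no genes have been lost
#' (descendant species set complete for its taxon). Missing bootstraps on
#' non-exempt nodes fail.
#'
#' @inheritParams node_age_class
#' @param gene1,gene2 Tip labels.
#' @param min_bootstrap Bootstrap threshold (percent).
#' @return Logical.
#' @export
support_confident <- function(tree, gene1, gene2, species_map, taxonomy,
                              min_bootstrap = 70) {
  mrca <- duplication_node(tree, gene1, gene2)
  bs <- .node_bootstrap(tree, mrca)
  if (is.na(bs) || bs < min_bootstrap) return(FALSE)
  ntip <- length(tree$tip.label)
  path_nodes <- unique(unlist(lapply(c(gene1, gene2), function(g) {
    tip <- which(tree$tip.label == g)
    nodes <- integer(0)
    cur <- .node_parent(tree, tip)
    while (!is.na(cur) && cur != mrca) {
      nodes <- c(nodes, cur)
      cur <- .node_parent(tree, cur)
    }
    nodes
  })))
  path_nodes <- path_nodes[path_nodes > ntip]
  for (nd in path_nodes) {
    b <- .node_bootstrap(tree, nd)
    if (!is.na(b) && b >= min_bootstrap) next
    if (.complete_speciation(nd, tree, species_map, taxonomy)) next
    return(FALSE)
  }
  TRUE
}

#' Date a duplicate pair across gene-tree releases
#'
#' Estimates the pair's age from each release in which both genes occur in
#' one family tree; the call is confident when at least two of the (up to
#' three) most recent releases agree on the class, or when the most recent
#' release's estimate is strongly supported ([support_confident()]). When
#' the two genes belong to different families, the pair is dated
#' `"Eukaryota"` provided both families contain the required deep taxa
#' (by default: a human gene, a Drosophila gene, and a yeast or Arabidopsis
#' outgroup gene). Otherwise the age is `"Unknown"`.
#'
#' @param trees List of rooted gene trees ordered oldest release first,
#'   most recent release last. Trees in which either gene is absent are
#'   skipped.
#' @param gene1,gene2 Gene ids.
#' @param species_map Named character vector, gene id to species (covering
#'   all trees and, if given, the family table).
#' @param taxonomy Species taxonomy (see [node_age_class()]).
#' @param families Optional data frame `gene_id`, `family_id` used for the
#'   split-family rule.
#' @param min_bootstrap Bootstrap threshold for strong support.
#' @param focal_species Focal lineage species.
#' @param eukaryota_rule List with `required` (species that must each be
#'   present in both families) and `any_of` (at least one must be present).
#' @return List with `age_class` (one of [age_classes()] or `"Unknown"`),
#'   `confident` and `basis` (`"multi-release-agreement"`,
#'   `"strong-support"`, `"family-split-rule"` or `NA`).
#' @export
date_pair <- function(trees, gene1, gene2, species_map, taxonomy,
                      families = NULL, min_bootstrap = 70,
                      focal_species = "c_elegans",
                      eukaryota_rule = list(
                        required = c("h_sapiens", "d_melanogaster"),
                        any_of = c("s_cerevisiae", "a_thaliana"))) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  usable <- Filter(function(tr) all(c(gene1, gene2) %in% tr$tip.label),
                   trees)
  unknown <- list(age_class = "Unknown", confident = FALSE,
                  basis = NA_character_)
  if (length(usable) > 0) {
    recent <- utils::tail(usable, 3)
    ages <- vapply(recent, function(tr) {
      node_age_class(duplication_node(tr, gene1, gene2), tr, species_map,
                     taxonomy, focal_species)
    }, character(1))
    tab <- table(ages)
    if (any(tab >= 2)) {
      return(list(age_class = names(tab)[which.max(tab)], confident = TRUE,
                  basis = "multi-release-agreement"))
    }
    newest <- recent[[length(recent)]]
    if (support_confident(newest, gene1, gene2, species_map, taxonomy,
                          min_bootstrap)) {
      return(list(age_class = ages[length(ages)], confident = TRUE,
                  basis = "strong-support"))
    }
  }
  if (!is.null(families)) {
    f1 <- families$family_id[match(gene1, families$gene_id)]
    f2 <- families$family_id[match(gene2, families$gene_id)]
    if (!is.na(f1) && !is.na(f2) && f1 != f2) {
      fam_species <- function(f) {
        g <- families$gene_id[families$family_id == f]
        unique(unname(species_map[intersect(g, names(species_map))]))
      }
      deep <- function(sp) {
        all(eukaryota_rule$required %in% sp) &&
          any(eukaryota_rule$any_of %in% sp)
      }
      if (deep(fam_species(f1)) && deep(fam_species(f2))) {
        return(list(age_class = "Eukaryota", confident = TRUE,
                    basis = "family-split-rule"))
      }
    }
  }
  unknown
}

#' Infer one-to-one orthologs between two species from a gene tree
#'
#' Candidate ortholog pairs are cross-species leaf pairs whose lowest common
#' ancestor is a speciation node (disjoint child species sets) with
#' bootstrap support at least `min_bootstrap`; the result is restricted to
#' one-to-one cases (each gene participating in exactly one candidate
#' pair).
#'
#' @param tree Rooted gene tree.
#' @param species_map Named character vector, gene id to species.
#' @param speciesA,speciesB The two species.
#' @param min_bootstrap Orthology bootstrap threshold; `NA` bootstraps fail
#'   unless the threshold is 0.
#' @return Data frame with columns `geneA`, `geneB`, `bootstrap`.
#' @export
infer_orthologs <- function(tree, species_map, speciesA, speciesB,
                            min_bootstrap = 70) {
  tipsA <- tree$tip.label[species_map[tree$tip.label] %in% speciesA]
  tipsB <- tree$tip.label[species_map[tree$tip.label] %in% speciesB]
  cand <- data.frame(geneA = character(), geneB = character(),
                     bootstrap = numeric(), stringsAsFactors = FALSE)
  for (a in tipsA) {
    for (b in tipsB) {
      mrca <- duplication_node(tree, a, b)
      if (!is_speciation_node(mrca, tree, species_map)) next
      bs <- .node_bootstrap(tree, mrca)
      if (min_bootstrap > 0 && (is.na(bs) || bs < min_bootstrap)) next
      cand <- rbind(cand, data.frame(geneA = a, geneB = b,
                                     bootstrap = if (is.na(bs)) NA_real_
                                                 else bs,
                                     stringsAsFactors = FALSE))
    }
  }
  one2one <- !(cand$geneA %in% cand$geneA[duplicated(cand$geneA)]) &
    !(cand$geneB %in% cand$geneB[duplicated(cand$geneB)])
  out <- cand[one2one, , drop = FALSE]
  rownames(out) <- NULL
  out
}
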