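#' Default species tree for gene-family simulation
#'
#' A rooted ultrametric ingroup tree of five allotetraploid clawed-frog
#' species, with branch lengths in expected substitutions per site.  Used as
#' the backbone on which [simulate_gene_families()] places a whole-genome
#' duplication that predates all ingroup speciation events.
#'
#' @return an `ape` phylo object with tips
#'   `xbor`, `xcli`, `xlae`, `xlar`, `xall` (root-to-tip depth 0.06).
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((xbor:0.03,xcli:0.03):0.03,",
    "(xlae:0.04,(xlar:0.02,xall:0.02):0.02):0.02);"))
}

#' Simulate allopolyploid gene families with known homeolog structure
#'
#' Each family evolves on a gene tree built from the ingroup species tree by
#' duplicating it at a whole-genome duplication (WGD) node that predates all
#' ingroup speciation (the allotetraploid situation: orthologs are more
#' closely related to each other than to homeologs), with an outgroup
#' attached below the WGD.  Sequences evolve under the Jukes-Cantor model.
#' Optional per-branch homeolog loss prunes clades from either duplicated
#' subtree, and optional splice-variant injection adds a near-identical
#' (approximately 99.8% identical) copy of a random tip, emulating the
#' transcript-assembly artifacts real families contain.
#'
#' @param n_families number of families to simulate.
#' @param species_tree rooted ultrametric ingroup species tree (default
#'   [default_species_tree()]); branch lengths in substitutions/site.
#' @param outgroup outgroup species label (default `"xtro"`).
#' @param wgd_stem branch length from the WGD node to each duplicated
#'   ingroup root (default 0.05).
#' @param outgroup_depth root-to-tip depth of the outgroup lineage
#'   (default 0.15); must exceed the WGD depth.
#' @param loss_prob per-branch probability that the clade below a branch of
#'   a duplicated subtree is lost (applied independently within each homeolog
#'   copy; the outgroup is never lost).
#' @param splice_variant_prob probability per family of injecting one
#'   splice-variant tip.
#' @param subst_rate rate multiplier applied to all branch lengths.
#' @param seq_length alignment length in bp (default 500).
#' @param duplication `"wgd"` (default), `"lineage_specific"` (no WGD; one
#'   random species gets a within-species duplication after speciation, the
#'   null case a homeolog filter must reject) or `"none"`.
#' @param seed optional integer seed.
#' @return a list of `n_families` elements, each a list with `family` (a
#'   [gene_family()], no tree attached), `true_tree` (the pruned gene tree)
#'   and `truth`: list with `partition` (the two true ortholog sets, tips
#'   named `species|1` and `species|2`; `NULL` when there is no WGD),
#'   `splice_tips` and `duplication`.
#' @export
simulate_gene_families <- function(n_families, species_tree = NULL,
                                   outgroup = "xtro", wgd_stem = 0.05,
                                   outgroup_depth = 0.15,
                                   loss_prob = 0, splice_variant_prob = 0,
                                   subst_rate = 1, seq_length = 500L,
                                   duplication = c("wgd", "lineage_specific",
                                                   "none"),
                                   seed = NULL) {
  duplication <- match.arg(duplication)
  if (is.null(species_tree)) species_tree <- default_species_tree()
  if (length(species_tree$tip.label) == 0L)
    stop("config error: species tree has no ingroup tips")
  stopifnot(seq_length >= 1L, loss_prob >= 0, loss_prob <= 1,
            splice_variant_prob >= 0, splice_variant_prob <= 1,
            subst_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_families), function(i)
    simulate_one_family(species_tree, outgroup, wgd_stem, outgroup_depth,
                        loss_prob, splice_variant_prob, subst_rate,
                        seq_length, duplication,
                        id = sprintf("fam%04d", i)))
}

simulate_one_family <- function(species_tree, outgroup, wgd_stem,
                                outgroup_depth, loss_prob,
                                splice_variant_prob, subst_rate, seq_length,
                                duplication, id) {
  depth <- max(ape::node.depth.edgelength(species_tree))
  if (duplication == "wgd") {
    copy_a <- relabel_tips(species_tree, "|1")
    copy_b <- relabel_tips(species_tree, "|2")
    copy_a <- apply_losses(copy_a, loss_prob)
    copy_b <- apply_losses(copy_b, loss_prob)
    gtree <- assemble_gene_tree(list(copy_a, copy_b), wgd_stem,
                                outgroup, outgroup_depth, depth)
  } else if (duplication == "lineage_specific") {
    base <- relabel_tips(species_tree, "|1")
    dup_sp <- sample(base$tip.label, 1L)
    base <- graft_duplicate(base, dup_sp, dup_depth = 0.015)
    gtree <- assemble_gene_tree(list(base), 0, outgroup, outgroup_depth,
                                depth)
  } else {
    base <- relabel_tips(species_tree, "|1")
    gtree <- assemble_gene_tree(list(base), 0, outgroup, outgroup_depth,
                                depth)
  }
  seqs <- simulate_sequences(gtree, seq_length, subst_rate)
  splice_tips <- character()
  if (splice_variant_prob > 0 && stats::runif(1L) < splice_variant_prob) {
    ingroup_tips <- setdiff(names(seqs), paste0(outgroup, "|O"))
    src <- sample(ingroup_tips, 1L)
    sv_name <- paste0(src, "sv")
    seqs[sv_name] <- mutate_sequence(seqs[[src]], 0.002)
    splice_tips <- sv_name
  }
  partition <- NULL
  if (duplication == "wgd") {
    tips <- setdiff(names(seqs), paste0(outgroup, "|O"))
    base <- sub("sv$", "", tips)  # splice tips belong to their source lineage
    partition <- list(sort(tips[endsWith(base, "|1")]),
                      sort(tips[endsWith(base, "|2")]))
  }
  fam <- gene_family(seqs, id = id)
  list(family = fam, true_tree = gtree,
       truth = list(partition = partition, splice_tips = splice_tips,
                    duplication = duplication))
}

# Replace one tip by a cherry of two copies diverging dup_depth before the
# present: a post-speciation (lineage-specific) duplication.
graft_duplicate <- function(tree, tip, dup_depth) {
  nwk <- ape::write.tree(tree)
  esc <- gsub("([|.])", "\\\\\\1", tip)
  rx <- paste0(esc, ":([0-9.eE+-]+)")
  len <- as.numeric(sub(paste0(".*", esc, ":([0-9.eE+-]+).*"), "\\1", nwk))
  d <- min(dup_depth, len / 2)
  cherry <- paste0("(", tip, ":", d, ",", sub("\\|1$", "|1b", tip), ":", d,
                   "):", len - d)
  ape::read.tree(text = sub(rx, cherry, nwk))
}

relabel_tips <- function(tree, suffix) {
  tree$tip.label <- paste0(tree$tip.label, suffix)
  tree
}

# Per-branch clade loss within one duplicated subtree.  Returns the pruned
# tree, or NULL when every tip is lost.
apply_losses <- function(tree, loss_prob) {
  if (loss_prob <= 0) return(tree)
  n_edge <- nrow(tree$edge)
  lost_edges <- which(stats::runif(n_edge) < loss_prob)
  if (!length(lost_edges)) return(tree)
  lost_tips <- unique(unlist(lapply(lost_edges, function(e) {
    node <- tree$edge[e, 2L]
    tips_below(tree, node)
  })))
  keep <- setdiff(tree$tip.label, lost_tips)
  if (length(keep) == 0L) return(NULL)
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1L]]]
}

# Build the full gene tree: duplicated ingroup copies joined at the WGD
# node, outgroup attached at the root.  Copies may be NULL (fully lost).
assemble_gene_tree <- function(copies, stem, outgroup, outgroup_depth,
                               ingroup_depth) {
  copies <- Filter(Negate(is.null), copies)
  if (length(copies) == 0L)
    return(ape::read.tree(text = paste0(outgroup, "|O:", outgroup_depth,
                                        ";")))
  nwk <- vapply(copies, function(tr) {
    s <- ape::write.tree(tr)
    sub(";$", "", s)
  }, "")
  if (length(nwk) == 2L) {
    ingroup <- paste0("(", nwk[1L], ":", stem, ",", nwk[2L], ":", stem, ")")
    wgd_depth <- ingroup_depth + stem
  } else {
    ingroup <- nwk[1L]
    wgd_depth <- ingroup_depth
  }
  root_edge <- outgroup_depth - wgd_depth
  if (root_edge < 0) stop("outgroup_depth must exceed the ingroup depth")
  txt <- paste0("(", ingroup, ":", root_edge, ",", outgroup, "|O:",
                outgroup_depth, ");")
  ape::read.tree(text = txt)
}

# Jukes-Cantor sequence simulation along a gene tree.
simulate_sequences <- function(tree, seq_length, subst_rate) {
  if (length(tree$tip.label) == 1L) {
    s <- paste(sample(c("A", "C", "G", "T"), seq_length, replace = TRUE),
               collapse = "")
    return(stats::setNames(s, tree$tip.label))
  }
  tr <- tree
  tr$edge.length <- tr$edge.length * subst_rate
  if (subst_rate == 0) tr$edge.length[] <- 0
  sim <- phangorn::simSeq(tr, l = seq_length, type = "DNA")
  m <- toupper(as.character(sim))
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}
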