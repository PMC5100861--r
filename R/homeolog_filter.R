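#' Configuration for the ortholog/homeolog filter
#'
#' @param min_ungapped_bp minimum ungapped alignment length (columns with no
#'   gap in any retained sequence); the default 300 keeps alignments whose
#'   ungapped length exceeds 299 bp.
#' @param min_ingroup_species minimum number of ingroup species (default 3).
#' @param max_rounds maximum number of tree-build-and-assess cycles
#'   (default 3).
#' @param outgroup outgroup species label used for rooting (midpoint rooting
#'   is used when no outgroup sequence is present).
#' @param prune_pdist p-distance at or below which two same-species
#'   sequences are treated as near-identical copies (splice variants,
#'   segmental duplicates or assembly errors) and pruned to the longest
#'   (default 0.01).
#' @param seed optional seed for any randomized tie-breaks.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_ungapped_bp = 300L, min_ingroup_species = 3L,
                          max_rounds = 3L, outgroup = "xtro",
                          prune_pdist = 0.01, seed = NULL) {
  stopifnot(max_rounds >= 1L, min_ungapped_bp >= 0L)
  structure(list(min_ungapped_bp = as.integer(min_ungapped_bp),
                 min_ingroup_species = as.integer(min_ingroup_species),
                 max_rounds = as.integer(max_rounds), outgroup = outgroup,
                 prune_pdist = prune_pdist, seed = seed),
            class = "filter_config")
}

#' Alignment-level quality control for gene families
#'
#' Passes a family iff (i) the ungapped alignment length (columns with no
#' gap in any sequence) is at least `config$min_ungapped_bp`, (ii) at least
#' `config$min_ingroup_species` ingroup species are present, and (iii) at
#' least one ingroup species contributes two or more sequences (without
#' which orthologs and homeologs cannot be told apart).
#'
#' @param family a [gene_family()].
#' @param config a [filter_config()].
#' @return list with `pass` (logical) and `reason` (`NA` when passing).
#' @export
alignment_qc <- function(family, config = filter_config()) {
  ingroup <- family$species[family$species != config$outgroup]
  ug <- ungapped_columns(family$seqs)
  if (ug < config$min_ungapped_bp)
    return(list(pass = FALSE,
                reason = sprintf("ungapped_length_%d_below_%d", ug,
                                 config$min_ungapped_bp)))
  if (length(unique(ingroup)) < config$min_ingroup_species)
    return(list(pass = FALSE, reason = "too_few_ingroup_species"))
  if (max(table(ingroup)) < 2L)
    return(list(pass = FALSE, reason = "no_species_with_two_sequences"))
  list(pass = TRUE, reason = NA_character_)
}

#' Neighbor-joining gene tree from pairwise p-distances
#'
#' Builds an unrooted tree with `ape`'s neighbor-joining from p-distances
#' computed with pairwise deletion of gap positions.  Sequences are ordered
#' by name before distance computation so ties resolve deterministically.
#'
#' @param family a [gene_family()] with at least 3 sequences.
#' @return an `ape` phylo (negative NJ branch lengths clamped to zero).
#' @export
build_nj_tree <- function(family) {
  if (length(family$seqs) < 3L)
    stop("need at least 3 sequences to build a tree, have ",
         length(family$seqs))
  dm <- p_distance_matrix(family$seqs)
  tr <- ape::nj(as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Assess whether a gene tree separates orthologs from homeologs
#'
#' The tree is rooted on the outgroup when present (midpoint otherwise) and
#' its internal nodes are searched in post-order for a node whose two child
#' clades form a valid homeolog partition of ingroup sequences: (a) each
#' clade holds at most one sequence per species, (b) at least one species
#' appears in both clades (its two copies diverged at the duplication, which
#' therefore predates speciation), and (c) at least one clade holds three or
#' more sequences.  Requiring both ortholog sets to be clades is what
#' rejects lineage-specific duplications: two same-species sequences that
#' are sisters to the exclusion of all other species can never sit in two
#' valid clades.
#'
#' When no valid node exists but some species contributes near-identical
#' sequences (p-distance at most `config$prune_pdist` — putative splice
#' variants or assembly duplicates), the assessment requests a prune that
#' keeps the longest sequence of each such cluster.  Otherwise the family is
#' rejected, with reason `sister_duplicates` when every multi-copy species
#' has only sister sequences, or `no_valid_partition`.
#'
#' @param family a [gene_family()] whose `tree` is set.
#' @param config a [filter_config()].
#' @return list with `action` (`"accept"`, `"prune"` or `"reject"`) and,
#'   depending on action, `partition` (list of two character vectors),
#'   `drop` (tips to remove) or `reason`.
#' @export
assess_homeology <- function(family, config = filter_config()) {
  if (is.null(family$tree)) stop("family has no tree; build one first")
  tree <- root_family_tree(family$tree, family$species, config$outgroup)
  ingroup_tips <- names(family$species)[family$species != config$outgroup]
  part <- search_partition(tree, family$species, ingroup_tips)
  if (!is.null(part))
    return(list(action = "accept", partition = part))
  drop <- near_identical_drop(family, ingroup_tips, config$prune_pdist)
  if (length(drop))
    return(list(action = "prune", drop = drop))
  multi <- names(which(table(family$species[ingroup_tips]) >= 2L))
  if (length(multi) == 0L)
    return(list(action = "reject", reason = "no_species_with_two_sequences"))
  reason <- if (all_duplicates_are_sisters(tree, family$species, multi))
    "sister_duplicates" else "no_valid_partition"
  list(action = "reject", reason = reason)
}

root_family_tree <- function(tree, species, outgroup) {
  out_tips <- names(species)[species == outgroup]
  out_tips <- intersect(out_tips, tree$tip.label)
  if (length(out_tips) > 0L) {
    if (length(out_tips) < length(tree$tip.label))
      tree <- ape::root(tree, outgroup = out_tips, resolve.root = TRUE)
  } else {
    if (length(tree$tip.label) <= 2L)
      stop("cannot root a tree with <= 2 tips and no outgroup")
    tree <- phangorn::midpoint(tree)
  }
  tree
}

# Post-order search over internal nodes for a valid child-clade pair.
search_partition <- function(tree, species, ingroup_tips) {
  # post-order: deeper nodes are visited before their ancestors
  internal <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1L])
  clades <- phangorn::Descendants(tree, type = "tips")
  for (node in internal) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    if (length(kids) < 2L) next
    kid_tips <- lapply(kids, function(k)
      intersect(tree$tip.label[clades[[k]]], ingroup_tips))
    # multifurcations: try each unordered pair of child clades
    for (i in seq_len(length(kid_tips) - 1L)) {
      for (j in seq(i + 1L, length(kid_tips))) {
        g1 <- kid_tips[[i]]; g2 <- kid_tips[[j]]
        if (valid_partition(g1, g2, species))
          return(list(sort(g1), sort(g2)))
      }
    }
  }
  NULL
}

valid_partition <- function(g1, g2, species) {
  if (length(g1) == 0L || length(g2) == 0L) return(FALSE)
  s1 <- species[g1]; s2 <- species[g2]
  if (anyDuplicated(s1) || anyDuplicated(s2)) return(FALSE)
  if (length(intersect(s1, s2)) < 1L) return(FALSE)
  max(length(g1), length(g2)) >= 3L
}

# Tips to drop: for every cluster of same-species sequences within
# prune_pdist of each other, keep the longest (ungapped); ties broken by
# name order.
near_identical_drop <- function(family, ingroup_tips, prune_pdist) {
  tab <- table(family$species[ingroup_tips])
  multi <- names(tab)[tab >= 2L]
  if (!length(multi)) return(character())
  dm <- p_distance_matrix(family$seqs)
  drop <- character()
  for (sp in multi) {
    tips <- sort(intersect(names(family$species)[family$species == sp],
                           ingroup_tips))
    sub <- dm[tips, tips, drop = FALSE]
    remaining <- tips
    while (length(remaining) >= 2L) {
      t1 <- remaining[1L]
      near <- remaining[sub[t1, remaining] <= prune_pdist]
      if (length(near) >= 2L) {
        lens <- vapply(family$seqs[near], ungapped_nchar, 0L)
        keep <- near[order(-lens, near)][1L]
        drop <- c(drop, setdiff(near, keep))
        remaining <- setdiff(remaining, near)
      } else {
        remaining <- remaining[-1L]
      }
    }
  }
  unique(drop)
}

all_duplicates_are_sisters <- function(tree, species, multi_species) {
  clades <- phangorn::Descendants(tree, type = "tips")
  internal <- unique(tree$edge[, 1L])
  for (sp in multi_species) {
    tips <- names(species)[species == sp]
    tips <- intersect(tips, tree$tip.label)
    is_sister_pair <- any(vapply(internal, function(node) {
      setequal(tree$tip.label[clades[[node]]], tips)
    }, TRUE))
    if (!is_sister_pair) return(FALSE)
  }
  TRUE
}

#' Run the multi-round ortholog/homeolog filter over gene families
#'
#' For each family: alignment QC, then up to `config$max_rounds` cycles of
#' tree building (the family's own tree is used in round one when provided;
#' neighbor joining otherwise) followed by [assess_homeology()].  A prune
#' request drops the indicated tips, re-runs QC and rebuilds the tree.
#' Families not resolved within `max_rounds` are rejected with reason
#' `unresolved_after_rounds`.
#'
#' @param families list of [gene_family()] objects.
#' @param config a [filter_config()].
#' @return list with `families` (the input list, statuses and partitions
#'   filled in, pruned tips removed) and `audit`, a data frame with one row
#'   per input family: `family_id`, `status`, `reason`, `rounds_used`,
#'   `n_seqs_in`, `n_seqs_out`, `partition` (pipe-separated).
#' @export
run_filter <- function(families, config = filter_config()) {
  audits <- vector("list", length(families))
  for (i in seq_along(families)) {
    fam <- families[[i]]
    if (is.null(fam$id))
      fam$id <- if (!is.null(names(families))) names(families)[i]
                else sprintf("fam%04d", i)
    n_in <- length(fam$seqs)
    rounds <- 0L
    repeat {
      qc <- alignment_qc(fam, config)
      if (!qc$pass) {
        fam$status <- "rejected"; fam$rejection_reason <- qc$reason
        break
      }
      if (rounds >= config$max_rounds) {
        fam$status <- "rejected"
        fam$rejection_reason <- "unresolved_after_rounds"
        break
      }
      rounds <- rounds + 1L
      if (is.null(fam$tree)) fam$tree <- build_nj_tree(fam)
      res <- assess_homeology(fam, config)
      if (res$action == "accept") {
        fam$status <- "accepted"; fam$partition <- res$partition
        break
      }
      if (res$action == "reject") {
        fam$status <- "rejected"; fam$rejection_reason <- res$reason
        break
      }
      fam$seqs <- fam$seqs[setdiff(names(fam$seqs), res$drop)]
      fam$species <- fam$species[names(fam$seqs)]
      fam$tree <- NULL
    }
    families[[i]] <- fam
    audits[[i]] <- data.frame(
      family_id = fam$id, status = fam$status,
      reason = fam$rejection_reason, rounds_used = rounds,
      n_seqs_in = n_in, n_seqs_out = length(fam$seqs),
      partition = if (fam$status == "accepted")
        paste(vapply(fam$partition, paste, "", collapse = ","),
              collapse = " | ") else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(families = families, audit = do.call(rbind, audits))
}

#' Reduce an accepted family for multispecies-coalescent analysis
#'
#' Keeps the ortholog set that covers every required species (the "complete
#' lineage") plus exactly one sequence from the other homeologous lineage:
#' the longest by ungapped length, with a seeded random choice among equally
#' long sequences.  Because the homeologous lineage diverged from all the
#' retained orthologs at the duplication, it does not matter which species
#' that extra sequence comes from.
#'
#' @param family an accepted [gene_family()].
#' @param required_species character vector of species that the complete
#'   lineage must cover.
#' @param seed optional seed for the tie-break draw.
#' @return list with `eligible` (logical), `family` (the reduced
#'   `gene_family`, or `NULL`), `kept_homeolog` (the sequence retained from
#'   the other lineage) and `reason` when not eligible.
#' @export
select_for_coalescent <- function(family, required_species, seed = NULL) {
  if (family$status != "accepted")
    return(list(eligible = FALSE, family = NULL, kept_homeolog = NA_character_,
                reason = "family_not_accepted"))
  covers <- vapply(family$partition, function(set)
    all(required_species %in% family$species[set]), TRUE)
  if (!any(covers))
    return(list(eligible = FALSE, family = NULL, kept_homeolog = NA_character_,
                reason = "no_lineage_covers_required_species"))
  complete <- family$partition[[which(covers)[1L]]]
  other <- family$partition[[setdiff(1:2, which(covers)[1L])]]
  if (length(other) == 0L)
    return(list(eligible = FALSE, family = NULL, kept_homeolog = NA_character_,
                reason = "other_lineage_empty"))
  lens <- vapply(family$seqs[other], ungapped_nchar, 0L)
  best <- other[lens == max(lens)]
  if (!is.null(seed)) set.seed(seed)
  kept <- if (length(best) == 1L) best else sample(best, 1L)
  keep_names <- c(complete, kept)
  out <- family
  out$seqs <- family$seqs[keep_names]
  out$species <- family$species[keep_names]
  out$tree <- NULL
  out$partition <- list(sort(complete), kept)
  list(eligible = TRUE, family = out, kept_homeolog = kept,
       reason = NA_character_)
}
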