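# Fixture builders and independent oracles used across the suite.

# Build a one-or-more-locus family dataset from explicit genotype rows.
# geno_rows: list of character vectors (mother, father, daughters..., sons...)
make_family <- function(geno_rows, n_daughters, n_sons,
                        locus_ids = paste0("L", seq_along(geno_rows))) {
  ids <- c("mom", "dad",
           if (n_daughters > 0) paste0("d", seq_len(n_daughters)),
           if (n_sons > 0) paste0("s", seq_len(n_sons)))
  geno <- do.call(rbind, geno_rows)
  dimnames(geno) <- list(locus_ids, ids)
  ind <- data.frame(
    id = ids,
    role = c("mother", "father", rep("offspring", n_daughters + n_sons)),
    sex = c("F", "M", rep("F", n_daughters), rep("M", n_sons)),
    stringsAsFactors = FALSE)
  family_dataset(geno, ind)
}

# One locus: mother, father, and per-sex offspring genotypes (recycled).
one_locus_family <- function(mother, father, daughters, sons,
                             n_daughters = length(daughters),
                             n_sons = length(sons)) {
  row <- c(mother, father, rep_len(daughters, n_daughters),
           rep_len(sons, n_sons))
  make_family(list(row), n_daughters, n_sons)
}

all_genotypes <- function(alleles = c("A", "C", "G", "T")) {
  combos <- expand.grid(a = alleles, b = alleles, stringsAsFactors = FALSE)
  unique(gt(combos$a, combos$b))
}

# Independent Mendelian oracle: brute-force enumeration of the four gamete
# combinations from the two parents.
oracle_mendel <- function(offspring_gt, mother_gt, father_gt) {
  if (is.na(mother_gt) || is.na(father_gt) || is.na(offspring_gt))
    return("unknown")
  m <- strsplit(mother_gt, "/")[[1]]
  f <- strsplit(father_gt, "/")[[1]]
  possible <- unique(c(gt(m[1], f[1]), gt(m[1], f[2]),
                       gt(m[2], f[1]), gt(m[2], f[2])))
  if (normalize_gt(offspring_gt) %in% possible) "plausible" else "implausible"
}

# Independent homeolog-acceptance oracle: enumerate every internal node of
# the rooted tree and every unordered pair of its child clades; accept iff
# some pair of ingroup-tip sets satisfies the partition criteria, checked
# with locally written predicates.
oracle_accepts <- function(rooted_tree, species, outgroup) {
  ingroup_tips <- names(species)[species != outgroup]
  clade_tips <- function(node) {
    ntip <- length(rooted_tree$tip.label)
    if (node <= ntip) return(rooted_tree$tip.label[node])
    kids <- rooted_tree$edge[rooted_tree$edge[, 1] == node, 2]
    unlist(lapply(kids, clade_tips))
  }
  ntip <- length(rooted_tree$tip.label)
  for (node in (ntip + 1):(ntip + rooted_tree$Nnode)) {
    kids <- rooted_tree$edge[rooted_tree$edge[, 1] == node, 2]
    if (length(kids) < 2) next
    sets <- lapply(kids, function(k) intersect(clade_tips(k), ingroup_tips))
    for (i in seq_len(length(sets) - 1)) {
      for (j in seq(i + 1, length(sets))) {
        g1 <- sets[[i]]; g2 <- sets[[j]]
        if (length(g1) == 0 || length(g2) == 0) next
        ok_a <- !anyDuplicated(species[g1]) && !anyDuplicated(species[g2])
        ok_b <- length(intersect(species[g1], species[g2])) >= 1
        ok_c <- max(length(g1), length(g2)) >= 3
        if (ok_a && ok_b && ok_c) return(TRUE)
      }
    }
  }
  FALSE
}

# Random gene family for the oracle suite: a random topology over tips drawn
# from a species pool (so some species recur), long branch lengths (no
# near-identical pairs), random unrelated sequences.
random_oracle_family <- function(n_tips, with_outgroup) {
  n_in <- n_tips - as.integer(with_outgroup)
  pool <- c("spA", "spB", "spC", "spD", "spE")
  sp <- sample(pool, n_in, replace = TRUE)
  counts <- stats::ave(seq_along(sp), sp, FUN = seq_along)
  tips <- paste0(sp, "|c", counts)
  if (with_outgroup) tips <- c(tips, "xtro|O")
  tr <- ape::rtree(length(tips), tip.label = sample(tips))
  tr$edge.length <- tr$edge.length + 0.5  # keep all pairs well separated
  seqs <- vapply(tips, function(t)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
    "")
  gene_family(seqs, tree = tr)
}

# Whether a simulated gene family's ground truth satisfies the filter's
# acceptance criteria (computed from truth alone, splice tips excluded).
truth_eligible <- function(sim_fam) {
  p <- lapply(sim_fam$truth$partition, setdiff, sim_fam$truth$splice_tips)
  if (is.null(p[[1]])) return(FALSE)
  spec_of <- function(x) sub("\\|.*", "", x)
  length(p[[1]]) > 0 && length(p[[2]]) > 0 &&
    length(intersect(spec_of(p[[1]]), spec_of(p[[2]]))) >= 1 &&
    max(lengths(p)) >= 3 &&
    length(unique(spec_of(unlist(p)))) >= 3
}

# Does the accepted partition equal the true homeolog split (restricted to
# surviving sequences)?
partition_matches_truth <- function(filtered_fam, sim_fam) {
  truth <- lapply(sim_fam$truth$partition,
                  function(s) sort(intersect(s, names(filtered_fam$seqs))))
  p <- lapply(filtered_fam$partition, sort)
  (setequal(truth[[1]], p[[1]]) && setequal(truth[[2]], p[[2]])) ||
    (setequal(truth[[1]], p[[2]]) && setequal(truth[[2]], p[[1]]))
}

# Aligned (gap-free) random sequence of given length.
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
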