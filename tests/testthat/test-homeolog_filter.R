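# Small helper: family from explicit sequences, optionally with a tree given
# as a newick string over the sequence names.
fam_from <- function(seqs, nwk = NULL) {
  tree <- if (!is.null(nwk)) ape::read.tree(text = nwk) else NULL
  gene_family(seqs, tree = tree)
}

test_that("alignment QC enforces exact length and species boundaries", {
  set.seed(1)
  base299 <- vapply(1:4, function(i) random_seq(299), "")
  names(base299) <- c("spA|1", "spA|2", "spB|1", "spC|1")
  expect_false(alignment_qc(gene_family(base299))$pass)   # 299 fails
  base300 <- vapply(1:4, function(i) random_seq(300), "")
  names(base300) <- names(base299)
  expect_true(alignment_qc(gene_family(base300))$pass)    # 300 passes
  # gap columns do not count toward ungapped length
  gapped <- base300
  gapped[1] <- paste0(substr(gapped[1], 1, 299), "-")
  expect_false(alignment_qc(gene_family(gapped))$pass)
  # 2 ingroup species fails, 3 passes
  two_sp <- base300[c("spA|1", "spA|2", "spB|1")]
  expect_equal(alignment_qc(gene_family(two_sp))$reason,
               "too_few_ingroup_species")
  # outgroup does not count as an ingroup species
  with_out <- c(base300[c("spA|1", "spA|2", "spB|1")],
                structure(random_seq(300), names = "xtro|O"))
  expect_equal(alignment_qc(gene_family(with_out))$reason,
               "too_few_ingroup_species")
  # no species with two sequences
  singles <- base300
  names(singles) <- c("spA|1", "spB|1", "spC|1", "spD|1")
  expect_equal(alignment_qc(gene_family(singles))$reason,
               "no_species_with_two_sequences")
})

test_that("neighbor joining reproduces the 3-taxon closed form", {
  # pairwise differences constructed on disjoint site sets:
  # d(a,b) = 0.10, d(a,c) = 0.20, d(b,c) = 0.30 over 100 sites
  a <- strsplit(random_seq(100), "")[[1]]
  flip <- function(x) chartr("ACGT", "TGCA", x)
  b <- a; b[1:10] <- flip(b[1:10])
  c_ <- a; c_[11:30] <- flip(c_[11:30])
  fam <- gene_family(c("sp1|a" = paste(a, collapse = ""),
                       "sp2|b" = paste(b, collapse = ""),
                       "sp3|c" = paste(c_, collapse = "")))
  tr <- build_nj_tree(fam)
  # three-point formulas: x_a = (dab+dac-dbc)/2 etc.
  lens <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens[c("sp1|a", "sp2|b", "sp3|c")]),
               c(0.0, 0.1, 0.2), tolerance = 1e-12)
})

test_that("neighbor joining recovers the additive quartet split", {
  # brute force over the 3 quartet topologies via the four-point condition
  set.seed(33)
  for (rep in 1:5) {
    tree <- ape::read.tree(text = sprintf(
      "((sp1|a:%.3f,sp2|b:%.3f):%.3f,sp3|c:%.3f,sp4|d:%.3f);",
      runif(1, .02, .08), runif(1, .02, .08), runif(1, .05, .15),
      runif(1, .02, .08), runif(1, .02, .08)))
    sim <- phangorn::simSeq(tree, l = 2000)
    m <- toupper(as.character(sim))
    seqs <- apply(m, 1, paste, collapse = "")
    fam <- gene_family(seqs)
    dm <- sexlinkr:::p_distance_matrix(fam$seqs)
    tips <- rownames(dm)
    sums <- c(dm[tips[1], tips[2]] + dm[tips[3], tips[4]],
              dm[tips[1], tips[3]] + dm[tips[2], tips[4]],
              dm[tips[1], tips[4]] + dm[tips[2], tips[3]])
    best <- which.min(sums)  # smallest pair-sum = the additive split
    nj <- build_nj_tree(fam)
    split_of <- function(t) {
      parts <- ape::prop.part(ape::unroot(t))
      sizes <- lengths(parts)
      inner <- parts[[which(sizes == 2)[1]]]
      sort(attr(parts, "labels")[inner])
    }
    pairs <- list(sort(c(tips[1], tips[2])), sort(c(tips[1], tips[3])),
                  sort(c(tips[1], tips[4])))
    got <- split_of(nj)
    expect_true(setequal(got, pairs[[best]]) ||
                setequal(setdiff(tips, got), pairs[[best]]))
  }
})

test_that("degenerate identical sequences give a zero-length deterministic tree", {
  s <- random_seq(50)
  fam <- gene_family(c("spA|1" = s, "spB|1" = s, "spC|1" = s))
  tr <- build_nj_tree(fam)
  expect_true(all(tr$edge.length == 0))
  tr2 <- build_nj_tree(fam)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # a pair with no comparable columns errors with the pair named
  g1 <- paste(c(rep("-", 25), strsplit(random_seq(25), "")[[1]]),
              collapse = "")
  g2 <- paste(c(strsplit(random_seq(25), "")[[1]], rep("-", 25)),
              collapse = "")
  expect_error(build_nj_tree(gene_family(c("spA|1" = g1, "spB|1" = g2,
                                           "spC|1" = random_seq(50)))),
               "spA\\|1.*spB\\|1|spB\\|1.*spA\\|1")
})

test_that("textbook duplication topologies are accepted with the right partition", {
  set.seed(2)
  seqs <- vapply(1:6, function(i) random_seq(40), "")
  names(seqs) <- c("spA|1", "spB|1", "spC|1", "spA|2", "spD|1", "xtro|O")
  fam <- fam_from(seqs,
    "(((spA|1:1,(spB|1:1,spC|1:1):1):1,(spA|2:1,spD|1:1):1):1,xtro|O:2);")
  res <- assess_homeology(fam)
  expect_equal(res$action, "accept")
  expect_equal(res$partition,
               list(c("spA|1", "spB|1", "spC|1"), c("spA|2", "spD|1")))
  # a lineage reduced to a single surviving sequence is still recognized
  fam1 <- fam_from(seqs[-5],
    "(((spA|1:1,(spB|1:1,spC|1:1):1):1,spA|2:2):1,xtro|O:2);")
  res1 <- assess_homeology(fam1)
  expect_equal(res1$action, "accept")
  expect_equal(res1$partition,
               list(c("spA|1", "spB|1", "spC|1"), "spA|2"))
})

test_that("sister same-species sequences are rejected as lineage-specific", {
  set.seed(3)
  seqs <- vapply(1:6, function(i) random_seq(40), "")
  names(seqs) <- c("spA|1", "spA|2", "spB|1", "spC|1", "spD|1", "xtro|O")
  fam <- fam_from(seqs, paste0(
    "(((spA|1:1,spA|2:1):1,(spB|1:1,(spC|1:1,spD|1:1):1):1):1,xtro|O:2);"))
  res <- assess_homeology(fam)
  expect_equal(res$action, "reject")
  expect_equal(res$reason, "sister_duplicates")
})

test_that("near-identical same-species tips trigger a prune of the shorter", {
  s <- random_seq(400)
  sv <- paste0(substr(s, 1, 395), "-----")  # shorter ungapped copy
  seqs <- c("spA|1" = s, "spA|1b" = sv,
            "spB|1" = random_seq(400), "spC|1" = random_seq(400))
  fam <- gene_family(seqs)
  fam$tree <- build_nj_tree(fam)
  res <- assess_homeology(fam)
  expect_equal(res$action, "prune")
  expect_equal(res$drop, "spA|1b")
})

test_that("acceptance decisions match exhaustive child-clade enumeration", {
  set.seed(77)
  cfg <- filter_config()
  n_accept <- 0
  for (i in 1:120) {
    n_tips <- sample(4:8, 1)
    with_out <- runif(1) < 0.7
    fam <- random_oracle_family(n_tips, with_out)
    if (!with_out && n_tips <= 2) next
    res <- assess_homeology(fam, cfg)
    rooted <- sexlinkr:::root_family_tree(fam$tree, fam$species,
                                          cfg$outgroup)
    want <- oracle_accepts(rooted, fam$species, cfg$outgroup)
    expect_equal(res$action == "accept", want,
                 info = ape::write.tree(fam$tree))
    if (want) {
      n_accept <- n_accept + 1
      expect_true(all(c(
        !anyDuplicated(fam$species[res$partition[[1]]]),
        !anyDuplicated(fam$species[res$partition[[2]]]),
        length(intersect(fam$species[res$partition[[1]]],
                         fam$species[res$partition[[2]]])) >= 1,
        max(lengths(res$partition)) >= 3)))
    }
  }
  expect_gt(n_accept, 5)  # the suite exercises both outcomes
})

test_that("run_filter resolves splice variants within the round budget", {
  fams <- simulate_gene_families(30, splice_variant_prob = 1, seed = 19)
  res <- run_filter(lapply(fams, `[[`, "family"))
  had_sv <- vapply(fams, function(f) length(f$truth$splice_tips) > 0, TRUE)
  acc <- res$audit$status == "accepted"
  expect_true(all(acc))
  expect_true(all(res$audit$rounds_used[had_sv] == 2))
  # pruned tips are gone from the output families
  for (i in which(had_sv))
    expect_false(any(fams[[i]]$truth$splice_tips %in%
                     names(res$families[[i]]$seqs)))
})

test_that("run_filter audit accounts for every family and never adds sequences", {
  fams <- simulate_gene_families(40, loss_prob = 0.3,
                                 splice_variant_prob = 0.2, seed = 23)
  short <- fams[[1]]$family
  short$seqs <- vapply(short$seqs, substr, "", 1, 100)  # fails length QC
  input <- c(list(short), lapply(fams, `[[`, "family"))
  res <- run_filter(input)
  expect_equal(nrow(res$audit), length(input))
  expect_true(all(res$audit$n_seqs_out <= res$audit$n_seqs_in))
  expect_match(res$audit$reason[1], "ungapped_length")
  expect_equal(res$audit$rounds_used[1], 0)
})

test_that("coalescent selection keeps the longest homeolog, seeded on ties", {
  set.seed(4)
  seqs <- c("spA|1" = random_seq(500), "spB|1" = random_seq(500),
            "spC|1" = random_seq(500),
            "spA|2" = paste0(substr(random_seq(500), 1, 400),
                             paste(rep("-", 100), collapse = "")),
            "spB|2" = random_seq(500))
  fam <- gene_family(seqs)
  fam$status <- "accepted"
  fam$partition <- list(c("spA|1", "spB|1", "spC|1"), c("spA|2", "spB|2"))
  sel <- select_for_coalescent(fam, c("spA", "spB", "spC"))
  expect_true(sel$eligible)
  expect_equal(sel$kept_homeolog, "spB|2")  # 500 > 400 ungapped
  expect_length(sel$family$seqs, 4L)
  # tie: seeded choice, stable across runs
  fam$seqs["spA|2"] <- random_seq(500)
  s1 <- select_for_coalescent(fam, c("spA", "spB", "spC"), seed = 9)
  s2 <- select_for_coalescent(fam, c("spA", "spB", "spC"), seed = 9)
  expect_equal(s1$kept_homeolog, s2$kept_homeolog)
  # single-sequence other lineage is kept as-is
  fam$partition <- list(c("spA|1", "spB|1", "spC|1"), "spA|2")
  expect_equal(select_for_coalescent(fam, c("spA", "spB", "spC"))
               $kept_homeolog, "spA|2")
  # ineligibility is reported, not raised
  miss <- select_for_coalescent(fam, c("spA", "spB", "spC", "spZ"))
  expect_false(miss$eligible)
  expect_equal(miss$reason, "no_lineage_covers_required_species")
})
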