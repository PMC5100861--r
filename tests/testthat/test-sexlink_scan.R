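test_that("completely sex-biased loci are detected and incomplete ones are not", {
  cand <- scan_sex_biased(one_locus_family("A/T", "A/A", "A/T", "A/A",
                                           n_daughters = 24, n_sons = 23))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$heterozygous_sex, "F")
  expect_equal(cand$het_daughters, 24)
  expect_equal(cand$hom_sons, 23)
  # all offspring homozygous: no candidate
  expect_equal(nrow(scan_sex_biased(one_locus_family(
    "A/T", "A/A", "A/A", "A/A", 24, 23))), 0L)
  # one homozygous daughter breaks completeness
  x <- one_locus_family("A/T", "A/A", c(rep("A/T", 23), "A/A"), "A/A",
                        n_daughters = 24, n_sons = 23)
  expect_equal(nrow(scan_sex_biased(x)), 0L)
})

test_that("low-information loci are skipped, not raised", {
  x <- one_locus_family("A/T", "A/A", "A/T", "A/A", n_daughters = 3,
                        n_sons = 8)
  out <- scan_sex_biased(x)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_skipped_low_information"), 1L)
  expect_equal(nrow(scan_sex_biased(x, scan_config(
    min_informative_per_sex = 3))), 1L)
})

test_that("require_all_offspring disqualifies loci with missing calls", {
  x <- one_locus_family("A/T", "A/A", c(rep("A/T", 23), NA), "A/A",
                        n_daughters = 24, n_sons = 23)
  expect_equal(nrow(scan_sex_biased(x)), 1L)
  expect_equal(nrow(scan_sex_biased(
    x, scan_config(require_all_offspring = TRUE))), 0L)
})

test_that("parental genotypes separate the four heterogamety patterns", {
  w <- scan_heterogamety(one_locus_family("A/T", "A/A", "A/T", "A/A", 24, 23))
  expect_equal(w$pattern, "W_pattern")
  z <- scan_heterogamety(one_locus_family("A/T", "A/A", "A/A", "A/T", 24, 23))
  expect_equal(z$pattern, "Z_pattern")
  y <- scan_heterogamety(one_locus_family("A/A", "A/T", "A/A", "A/T", 24, 23))
  expect_equal(y$pattern, "Y_pattern")
  xp <- scan_heterogamety(one_locus_family("A/A", "A/T", "A/T", "A/A", 24, 23))
  expect_equal(xp$pattern, "X_pattern")
  # both parents heterozygous: underdetermined
  both <- scan_heterogamety(one_locus_family("A/T", "A/T", "A/T", "A/A",
                                             24, 23))
  expect_equal(both$pattern, "inconsistent")
  # missing parent: unassessable, distinct from inconsistent
  na_mom <- scan_heterogamety(one_locus_family(NA, "A/A", "A/T", "A/A",
                                               24, 23))
  expect_equal(na_mom$pattern, "unassessable")
})

test_that("Mendelian-inconsistent sex-biased loci are demoted", {
  # daughters heterozygous C/G cannot come from A/T x A/A parents
  x <- one_locus_family("A/T", "A/A", "C/G", "A/A", 24, 23)
  expect_equal(scan_heterogamety(x)$pattern, "inconsistent")
})

test_that("classified calls pass the Mendelian check for all offspring used", {
  sim <- simulate_family(n_autosomal = 200, n_sexlinked = c(W = 10, Z = 3),
                         system = "ZW", seed = 17)
  calls <- scan_heterogamety(sim$dataset)
  x <- sim$dataset
  for (i in seq_len(nrow(calls))) {
    flags <- mendel_check(x$geno[calls$locus_id[i], offspring_ids(x)],
                          calls$mother_gt[i], calls$father_gt[i])
    expect_false(any(flags == "implausible"))
  }
})

test_that("system inference tallies patterns into a verdict", {
  calls <- data.frame(pattern = c(rep("W_pattern", 24), "Z_pattern"))
  v <- infer_system(calls)
  expect_equal(v$system, "ZZ/ZW")
  expect_equal(unname(v$tally[c("W_pattern", "Z_pattern")]), c(24L, 1L))
  expect_equal(infer_system(data.frame(pattern = character()))$system,
               "UNDETERMINED")
  mixed <- infer_system(data.frame(pattern = c(rep("W_pattern", 3),
                                               rep("Y_pattern", 3))))
  expect_equal(mixed$system, "CONFLICTING")
  expect_equal(unname(mixed$tally[c("W_pattern", "Y_pattern")]), c(3L, 3L))
  # inconsistent calls do not block a verdict
  expect_equal(infer_system(data.frame(
    pattern = c("X_pattern", "inconsistent")))$system, "XX/XY")
})

test_that("swapping sex and parent labels maps W->Y and Z->X exactly", {
  for (seed in c(3, 14)) {
    sim <- simulate_family(n_autosomal = 150, n_sexlinked = c(W = 8, Z = 2),
                           system = "ZW", undercall_rate = 0.1,
                           missing_rate = 0.05, seed = seed)
    qc <- qc_pipeline(sim$dataset)
    calls <- scan_heterogamety(qc$dataset)
    mirrored <- scan_heterogamety(qc_pipeline(
      swap_sex_labels(sim$dataset))$dataset)
    map <- c(W_pattern = "Y_pattern", Z_pattern = "X_pattern",
             X_pattern = "Z_pattern", Y_pattern = "W_pattern",
             inconsistent = "inconsistent", unassessable = "unassessable")
    expect_equal(mirrored$locus_id, calls$locus_id)
    expect_equal(mirrored$pattern, unname(map[calls$pattern]))
    v1 <- infer_system(calls); v2 <- infer_system(mirrored)
    if (v1$system == "ZZ/ZW") expect_equal(v2$system, "XX/XY")
  }
})
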