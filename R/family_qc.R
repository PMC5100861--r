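#' QC configuration for family genotype data
#'
#' @param max_implausible_frac loci where the fraction of called offspring
#'   with a Mendelian-implausible genotype is at least this value are
#'   discarded; below it the implausible cells are set to missing
#'   (default 0.10).
#' @param min_call_rate minimum fraction of individuals with a non-missing
#'   call for a locus to be retained (default 0.90).
#' @param call_rate_includes_parents whether the call-rate denominator counts
#'   the parents as well as the offspring (default `TRUE`).
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(max_implausible_frac = 0.10, min_call_rate = 0.90,
                      call_rate_includes_parents = TRUE) {
  stopifnot(max_implausible_frac >= 0, max_implausible_frac <= 1,
            min_call_rate >= 0, min_call_rate <= 1)
  structure(list(max_implausible_frac = max_implausible_frac,
                 min_call_rate = min_call_rate,
                 call_rate_includes_parents = call_rate_includes_parents),
            class = "qc_config")
}

#' Mendelian plausibility of offspring genotypes
#'
#' An offspring genotype is plausible if and only if it can be formed by
#' taking one allele from the mother and one from the father.  With parents
#' A/T and A/A, for example, an offspring T/T is implausible: when parents
#' are sequenced at much higher coverage than offspring, such a call usually
#' reflects allele dropout of a true heterozygote.
#'
#' @param offspring_gt character vector of offspring genotypes (`"A/T"`
#'   style, `NA` = missing).
#' @param mother_gt,father_gt single parental genotypes.
#' @return character vector over offspring with values `"plausible"`,
#'   `"implausible"` or `"unknown"` (missing offspring call, or either parent
#'   missing).
#' @export
mendel_check <- function(offspring_gt, mother_gt, father_gt) {
  n <- length(offspring_gt)
  if (is.na(mother_gt) || is.na(father_gt))
    return(rep("unknown", n))
  out <- rep("unknown", n)
  called <- !is.na(offspring_gt)
  o1 <- gt_allele(offspring_gt, 1L)
  o2 <- gt_allele(offspring_gt, 2L)
  m <- c(gt_allele(mother_gt, 1L), gt_allele(mother_gt, 2L))
  f <- c(gt_allele(father_gt, 1L), gt_allele(father_gt, 2L))
  ok <- (o1 %in% m & o2 %in% f) | (o2 %in% m & o1 %in% f)
  out[called] <- ifelse(ok[called], "plausible", "implausible")
  out
}

# Vectorized plausibility over the whole dataset.  Returns a loci x offspring
# matrix: TRUE plausible, FALSE implausible, NA unknown (missing offspring
# call or missing parent).
plausibility_matrix <- function(x) {
  off <- x$geno[, offspring_ids(x), drop = FALSE]
  mo <- x$geno[, mother_id(x)]
  fa <- x$geno[, father_id(x)]
  o1 <- gt_allele(off, 1L); o2 <- gt_allele(off, 2L)
  m1 <- gt_allele(mo, 1L); m2 <- gt_allele(mo, 2L)
  f1 <- gt_allele(fa, 1L); f2 <- gt_allele(fa, 2L)
  # per-locus parent vectors recycle down the columns of the offspring matrix
  in_m_1 <- (o1 == m1) | (o1 == m2)
  in_m_2 <- (o2 == m1) | (o2 == m2)
  in_f_1 <- (o1 == f1) | (o1 == f2)
  in_f_2 <- (o2 == f1) | (o2 == f2)
  plaus <- (in_m_1 & in_f_2) | (in_m_2 & in_f_1)
  dim(plaus) <- dim(off)
  dimnames(plaus) <- dimnames(off)
  plaus[is.na(mo) | is.na(fa), ] <- NA
  plaus
}

#' Correct heterozygote undercalling via Mendelian-implausibility screening
#'
#' Per locus, offspring genotypes that cannot be formed from one allele of
#' each parent are counted.  Writing `f` for the implausible fraction among
#' offspring with non-missing calls: if `f` is below
#' `config$max_implausible_frac` the implausible cells are set to missing and
#' the locus is kept (action `"corrected"`, or `"kept"` when there were
#' none); otherwise the locus is discarded (`"discarded_implausible"`).
#' Loci where either parent's genotype is missing pass through unmodified and
#' are flagged `parent_missing` in the report.
#'
#' @param x a [family_dataset()].
#' @param config a [qc_config()].
#' @return list with elements `dataset` (the corrected `family_dataset`) and
#'   `report` (a data frame with columns `locus_id`, `n_offspring_called`,
#'   `n_implausible`, `action`, `parent_missing`, plus attribute
#'   `corrected_cells`, a data frame of `(locus_id, individual_id)` pairs
#'   that were blanked).
#' @export
undercall_correct <- function(x, config = qc_config()) {
  if (nrow(x$geno) == 0L) {
    rep <- data.frame(locus_id = character(), n_offspring_called = integer(),
                      n_implausible = integer(), action = character(),
                      parent_missing = logical(), stringsAsFactors = FALSE)
    attr(rep, "corrected_cells") <-
      data.frame(locus_id = character(), individual_id = character())
    return(list(dataset = x, report = rep))
  }
  plaus <- plausibility_matrix(x)
  n_called <- rowSums(!is.na(plaus))
  n_impl <- rowSums(!plaus, na.rm = TRUE)
  parent_missing <- is.na(x$geno[, mother_id(x)]) | is.na(x$geno[, father_id(x)])
  f <- ifelse(n_called > 0L, n_impl / n_called, 0)
  discard <- !parent_missing & f >= config$max_implausible_frac & n_impl > 0L
  correct <- !parent_missing & !discard & n_impl > 0L
  action <- ifelse(parent_missing, "kept",
                   ifelse(discard, "discarded_implausible",
                          ifelse(correct, "corrected", "kept")))
  # blank implausible cells on corrected loci
  bad <- !plaus & !is.na(plaus) & matrix(correct, nrow(plaus), ncol(plaus))
  cells <- which(bad, arr.ind = TRUE)
  corrected_cells <- data.frame(
    locus_id = rownames(plaus)[cells[, 1L]],
    individual_id = colnames(plaus)[cells[, 2L]],
    stringsAsFactors = FALSE)
  if (nrow(cells) > 0L) {
    off_cols <- match(colnames(plaus), colnames(x$geno))
    x$geno[cbind(cells[, 1L], off_cols[cells[, 2L]])] <- NA_character_
  }
  report <- data.frame(locus_id = rownames(x$geno),
                       n_offspring_called = as.integer(n_called),
                       n_implausible = as.integer(n_impl),
                       action = action, parent_missing = parent_missing,
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "corrected_cells") <- corrected_cells
  x <- subset_loci(x, !discard)
  list(dataset = x, report = report)
}

#' Trim loci by genotype call rate
#'
#' Keeps loci whose fraction of non-missing calls is at least
#' `config$min_call_rate`.  The denominator is all individuals (parents
#' included) by default, or offspring only when
#' `config$call_rate_includes_parents` is `FALSE`.  Locus order is preserved.
#'
#' @inheritParams undercall_correct
#' @return list with `dataset` (trimmed) and `report` (data frame with
#'   `locus_id`, `call_rate`, `action` of `"kept"`/`"discarded_call_rate"`).
#' @export
call_rate_filter <- function(x, config = qc_config()) {
  cols <- if (config$call_rate_includes_parents) colnames(x$geno)
          else offspring_ids(x)
  g <- x$geno[, cols, drop = FALSE]
  rate <- rowSums(!is.na(g)) / length(cols)
  keep <- rate >= config$min_call_rate
  report <- data.frame(locus_id = rownames(x$geno), call_rate = rate,
                       action = ifelse(keep, "kept", "discarded_call_rate"),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(dataset = subset_loci(x, keep), report = report)
}

#' Full family-genotype QC pipeline
#'
#' Applies [call_rate_filter()] first and [undercall_correct()] second, the
#' order in which raw GBS genotype tables are normally trimmed (call-rate
#' trimming removes the bulk of poorly genotyped tags before the
#' parent-offspring comparison is made).
#'
#' @inheritParams undercall_correct
#' @return list with `dataset` and the two reports (`call_rate_report`,
#'   `undercall_report`).
#' @export
qc_pipeline <- function(x, config = qc_config()) {
  s1 <- call_rate_filter(x, config)
  s2 <- undercall_correct(s1$dataset, config)
  list(dataset = s2$dataset,
       call_rate_report = s1$report,
       undercall_report = s2$report)
}
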