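#' Configuration for the completely-sex-biased scan
#'
#' @param min_informative_per_sex minimum number of offspring of each sex
#'   with a non-missing call for a locus to be assessable (default 5).
#' @param require_all_offspring if `TRUE`, the complete-sex-bias predicate is
#'   evaluated over all offspring, so any missing offspring call disqualifies
#'   the locus; by default it is evaluated over non-missing calls only.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(min_informative_per_sex = 5L,
                        require_all_offspring = FALSE) {
  stopifnot(min_informative_per_sex >= 1L)
  structure(list(min_informative_per_sex = as.integer(min_informative_per_sex),
                 require_all_offspring = require_all_offspring),
            class = "scan_config")
}

#' Scan for completely sex-biased loci
#'
#' A locus is completely sex-biased when, among offspring with non-missing
#' calls, every individual of one sex is heterozygous and every individual of
#' the other sex is homozygous.  Offspring of unknown sex (`"U"`) are
#' ignored.  Loci with fewer informative offspring than
#' `config$min_informative_per_sex` in either sex are skipped (counted in the
#' attribute `n_skipped_low_information`).
#'
#' @param x a QC'd [family_dataset()].
#' @param config a [scan_config()].
#' @return data frame of candidate loci with columns `locus_id`,
#'   `heterozygous_sex` (`"F"` or `"M"`), `het_daughters`, `hom_daughters`,
#'   `het_sons`, `hom_sons`, `n_missing_F`, `n_missing_M`.
#' @export
scan_sex_biased <- function(x, config = scan_config()) {
  fem <- offspring_of_sex(x, "F")
  mal <- offspring_of_sex(x, "M")
  het <- is_het(x$geno)
  hF <- het[, fem, drop = FALSE]
  hM <- het[, mal, drop = FALSE]
  het_F <- rowSums(hF, na.rm = TRUE);  cal_F <- rowSums(!is.na(hF))
  het_M <- rowSums(hM, na.rm = TRUE);  cal_M <- rowSums(!is.na(hM))
  hom_F <- cal_F - het_F;  hom_M <- cal_M - het_M
  informative <- cal_F >= config$min_informative_per_sex &
                 cal_M >= config$min_informative_per_sex
  if (config$require_all_offspring)
    informative <- informative & cal_F == length(fem) & cal_M == length(mal)
  f_het <- het_F == cal_F & hom_M == cal_M
  m_het <- het_M == cal_M & hom_F == cal_F
  cand <- informative & (f_het | m_het)
  out <- data.frame(
    locus_id = rownames(x$geno)[cand],
    heterozygous_sex = ifelse(f_het[cand], "F", "M"),
    het_daughters = het_F[cand], hom_daughters = hom_F[cand],
    het_sons = het_M[cand], hom_sons = hom_M[cand],
    n_missing_F = length(fem) - cal_F[cand],
    n_missing_M = length(mal) - cal_M[cand],
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_skipped_low_information") <- sum(!informative)
  out
}

#' Classify a sex-biased locus as a W, Z, X or Y inheritance pattern
#'
#' Given a completely sex-biased locus and the parental genotypes, the
#' pattern is read off the parents: a heterozygous mother with a homozygous
#' father indicates female heterogamety, and heterozygous daughters then mark
#' a W-borne allele (`W_pattern`) while heterozygous sons mark a variant on
#' the maternal Z (`Z_pattern`).  The paternal mirror (father heterozygous,
#' mother homozygous) gives `Y_pattern` (sons heterozygous) or `X_pattern`
#' (daughters heterozygous).  Loci where both parents are heterozygous, both
#' homozygous, or where any offspring call used is Mendelian-implausible,
#' are `inconsistent`; a missing parental genotype gives `unassessable`.
#'
#' @param x a [family_dataset()].
#' @param candidates data frame from [scan_sex_biased()].
#' @return data frame of sex-linkage calls: the candidate columns plus
#'   `mother_gt`, `father_gt` and `pattern` in
#'   `W_pattern`/`Z_pattern`/`X_pattern`/`Y_pattern`/`inconsistent`/
#'   `unassessable`.
#' @export
classify_heterogamety <- function(x, candidates) {
  mo <- x$geno[candidates$locus_id, mother_id(x)]
  fa <- x$geno[candidates$locus_id, father_id(x)]
  off_ids <- offspring_ids(x)
  pattern <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    pattern[i] <- classify_one(
      mo[i], fa[i], candidates$heterozygous_sex[i],
      x$geno[candidates$locus_id[i], off_ids])
  }
  out <- candidates
  out$mother_gt <- unname(mo)
  out$father_gt <- unname(fa)
  out$pattern <- pattern
  out
}

classify_one <- function(mother_gt, father_gt, het_sex, offspring_gt) {
  if (is.na(mother_gt) || is.na(father_gt)) return("unassessable")
  m_het <- is_het(mother_gt)
  f_het <- is_het(father_gt)
  if (m_het == f_het) return("inconsistent")  # both het or both hom
  flags <- mendel_check(offspring_gt, mother_gt, father_gt)
  if (any(flags == "implausible")) return("inconsistent")
  if (m_het) {
    if (het_sex == "F") "W_pattern" else "Z_pattern"
  } else {
    if (het_sex == "M") "Y_pattern" else "X_pattern"
  }
}

#' Scan and classify in one step
#'
#' Convenience wrapper: [scan_sex_biased()] followed by
#' [classify_heterogamety()].
#'
#' @inheritParams scan_sex_biased
#' @return the classified calls data frame (see [classify_heterogamety()]).
#' @export
scan_heterogamety <- function(x, config = scan_config()) {
  classify_heterogamety(x, scan_sex_biased(x, config))
}

#' Infer the heterogamety system from classified calls
#'
#' Tallies the W/Z/X/Y patterns.  If every informative call is W or Z the
#' family shows female heterogamety (`"ZZ/ZW"`); if every call is X or Y,
#' male heterogamety (`"XX/XY"`); a mix is `"CONFLICTING"`, and no
#' informative calls at all is `"UNDETERMINED"`.  `inconsistent` and
#' `unassessable` calls are excluded from the verdict but reported in the
#' tally.
#'
#' @param calls data frame from [classify_heterogamety()] or
#'   [scan_heterogamety()].
#' @return list of class `system_call` with elements `system` and `tally`
#'   (named integer vector over all patterns seen).
#' @export
infer_system <- function(calls) {
  lv <- c("W_pattern", "Z_pattern", "X_pattern", "Y_pattern",
          "inconsistent", "unassessable")
  tally <- table(factor(calls$pattern, levels = lv))
  informative <- tally[c("W_pattern", "Z_pattern", "X_pattern", "Y_pattern")]
  zw <- sum(informative[c("W_pattern", "Z_pattern")])
  xy <- sum(informative[c("X_pattern", "Y_pattern")])
  system <- if (zw + xy == 0L) "UNDETERMINED"
            else if (xy == 0L) "ZZ/ZW"
            else if (zw == 0L) "XX/XY"
            else "CONFLICTING"
  structure(list(system = system, tally = c(tally)), class = "system_call")
}

#' @export
print.system_call <- function(x, ...) {
  cat("Heterogamety verdict:", x$system, "\n")
  shown <- x$tally[x$tally > 0L]
  if (length(shown))
    cat(paste0("  ", names(shown), ": ", shown, collapse = "\n"), "\n")
  invisible(x)
}
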