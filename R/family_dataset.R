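#' Family genotype dataset
#'
#' Container for a biallelic genotype matrix from a single two-parent family
#' cross, together with the pedigree roles and offspring sexes.  This is the
#' object all family-based QC and sex-linkage scans operate on.
#'
#' @param geno character matrix of normalized genotypes (see [gt()]), loci in
#'   rows and individuals in columns; `NA` marks missing calls.  Row names are
#'   locus ids, column names individual ids.
#' @param individuals data frame with columns `id`, `role` (one of `mother`,
#'   `father`, `offspring`) and `sex` (`F`, `M` or `U`), in the column order
#'   of `geno`.
#' @return an object of class `family_dataset`: a list with elements `geno`,
#'   `individuals` and `loci` (per-locus allele sets and a multiallelic flag).
#' @details Invariants enforced: exactly one mother and one father; unique
#'   individual ids; every genotype column matches the pedigree; genotype
#'   symbols are nucleotides.  Loci with more than two observed alleles are
#'   kept but flagged `multiallelic`.
#' @export
family_dataset <- function(geno, individuals) {
  if (!is.matrix(geno) || !is.character(geno))
    stop("`geno` must be a character matrix (loci x individuals)")
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  req <- c("id", "role", "sex")
  if (!all(req %in% names(individuals)))
    stop("`individuals` needs columns id, role, sex")
  individuals$id <- as.character(individuals$id)
  individuals$role <- as.character(individuals$role)
  individuals$sex <- as.character(individuals$sex)
  if (anyDuplicated(individuals$id))
    stop("pedigree error: duplicate individual ids: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  if (!all(individuals$role %in% c("mother", "father", "offspring")))
    stop("pedigree error: role must be mother, father or offspring")
  if (!all(individuals$sex %in% c("F", "M", "U")))
    stop("pedigree error: sex must be F, M or U")
  if (sum(individuals$role == "mother") != 1L)
    stop("pedigree error: need exactly one mother, found ",
         sum(individuals$role == "mother"))
  if (sum(individuals$role == "father") != 1L)
    stop("pedigree error: need exactly one father, found ",
         sum(individuals$role == "father"))
  if (ncol(geno) != nrow(individuals))
    stop("genotype matrix has ", ncol(geno), " columns but pedigree lists ",
         nrow(individuals), " individuals")
  if (is.null(colnames(geno))) colnames(geno) <- individuals$id
  if (!identical(colnames(geno), individuals$id))
    stop("reconciliation error: genotype columns do not match pedigree ids")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("locus", seq_len(nrow(geno)), recycle0 = TRUE)
  geno <- normalize_gt(geno)
  bad <- !is.na(geno) &
    !(gt_allele(geno, 1L) %in% VALID_ALLELES &
      gt_allele(geno, 2L) %in% VALID_ALLELES)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop("parse error: invalid genotype token '", geno[bad][1L],
         "' at locus ", rownames(geno)[i[1L]])
  }
  loci <- locus_table(geno)
  structure(list(geno = geno, individuals = individuals, loci = loci),
            class = "family_dataset")
}

locus_table <- function(geno) {
  alleles <- apply(geno, 1L, function(g) {
    a <- unique(c(gt_allele(g, 1L), gt_allele(g, 2L)))
    paste(sort(a[!is.na(a)]), collapse = ",")
  })
  n_alleles <- ifelse(alleles == "", 0L, nchar(gsub("[^,]", "", alleles)) + 1L)
  data.frame(locus_id = rownames(geno), alleles = alleles,
             multiallelic = n_alleles > 2L, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.family_dataset <- function(x, ...) {
  cat("family_dataset:", nrow(x$geno), "loci x", ncol(x$geno), "individuals\n")
  off <- x$individuals[x$individuals$role == "offspring", ]
  cat("  offspring:", sum(off$sex == "F"), "daughters,",
      sum(off$sex == "M"), "sons,", sum(off$sex == "U"), "unknown sex\n")
  cat("  missing calls:", sum(is.na(x$geno)), sprintf(
    "(%.1f%%)\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @rdname family_dataset
#' @param x a `family_dataset`.
#' @export
mother_id <- function(x) x$individuals$id[x$individuals$role == "mother"]

#' @rdname family_dataset
#' @export
father_id <- function(x) x$individuals$id[x$individuals$role == "father"]

#' @rdname family_dataset
#' @export
offspring_ids <- function(x) x$individuals$id[x$individuals$role == "offspring"]

# Offspring ids of a given sex ("F"/"M"); sex "U" offspring are never returned.
offspring_of_sex <- function(x, sex) {
  i <- x$individuals$role == "offspring" & x$individuals$sex == sex
  x$individuals$id[i]
}

# Subset loci, keeping pedigree intact.
subset_loci <- function(x, keep) {
  x$geno <- x$geno[keep, , drop = FALSE]
  x$loci <- x$loci[match(rownames(x$geno), x$loci$locus_id), , drop = FALSE]
  rownames(x$loci) <- NULL
  x
}

#' Swap sex and parent labels of a family dataset
#'
#' Relabels the mother as father (and vice versa) and every offspring's sex
#' F as M (and vice versa), leaving genotypes untouched.  Under this
#' relabeling a W-pattern marker becomes a Y-pattern marker and a Z-pattern
#' becomes an X-pattern, which is the symmetry used to validate the
#' heterogamety classifier.
#'
#' @param x a `family_dataset`.
#' @return a `family_dataset` with swapped labels.
#' @export
swap_sex_labels <- function(x) {
  ind <- x$individuals
  ind$role <- c(mother = "father", father = "mother",
                offspring = "offspring")[ind$role]
  ind$sex <- c(F = "M", M = "F", U = "U")[ind$sex]
  family_dataset(x$geno, ind)
}
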