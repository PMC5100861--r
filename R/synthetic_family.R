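#' Simulate a GBS-style family cross with known truth
#'
#' Generates a biallelic genotype matrix for a two-parent family emulating a
#' reduced-representation (GBS) experiment: a set of autosomal tags
#' segregating Mendelianly, a fully sex-linked (non-recombining) tag class
#' under either female (ZW) or male (XY) heterogamety, heterozygote
#' undercalling (allele dropout) concentrated in offspring because the
#' parents are sequenced at much higher coverage, and random missingness.
#'
#' Defaults mirror a cross of 24 daughters and 23 sons.  Under ZW, a
#' `W`-class locus gives the mother a W-specific allele transmitted to all
#' daughters and no sons (mother and daughters heterozygous, father and sons
#' homozygous); a `Z`-class locus puts the variant on the maternal Z (mother
#' and sons heterozygous).  Under XY the father carries the linked variant
#' and `Y`/`X` classes mirror `W`/`Z`.  Parental genotypes at autosomal loci
#' are drawn uniformly from the seven ordered parent-genotype pairs that
#' leave the locus polymorphic in the family, reflecting that reference-free
#' SNP callers only report polymorphic tags.
#'
#' @param n_daughters,n_sons offspring counts (defaults 24 and 23).
#' @param n_autosomal number of autosomal loci.
#' @param n_sexlinked number of fully sex-linked loci.  Either a single count
#'   (all loci carry the sex-limited-chromosome allele: class `W` under ZW,
#'   `Y` under XY) or a named vector splitting classes, e.g.
#'   `c(W = 25, Z = 1)` under ZW or `c(Y = 25, X = 1)` under XY.
#' @param system `"ZW"` or `"XY"`; required when `n_sexlinked > 0`.
#' @param undercall_rate probability that a heterozygous offspring call is
#'   read as one of its two homozygotes (chosen with equal probability).
#' @param missing_rate probability that an offspring call is missing
#'   (applied after undercalling).
#' @param parent_error_scale multiplier (< 1) applied to both error rates for
#'   the parents, reflecting their roughly 10-fold higher coverage
#'   (default 0.1).
#' @param seed optional integer seed; fixed seed gives reproducible output.
#' @return list with `dataset` (a [family_dataset()]) and `truth`, a list
#'   with `loci` (data frame of `locus_id`, `class` in
#'   `autosomal`/`W_linked`/`Z_linked`/`X_linked`/`Y_linked`) and
#'   `geno_true` (the genotype matrix before any error process).
#' @export
simulate_family <- function(n_daughters = 24L, n_sons = 23L,
                            n_autosomal = 100L, n_sexlinked = 0L,
                            system = c("ZW", "XY"),
                            undercall_rate = 0, missing_rate = 0,
                            parent_error_scale = 0.1, seed = NULL) {
  stopifnot(n_daughters >= 0L, n_sons >= 0L, n_autosomal >= 0L,
            undercall_rate >= 0, undercall_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            parent_error_scale >= 0, parent_error_scale <= 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- expand_sexlinked_classes(n_sexlinked, system)
  system <- if (length(classes)) match.arg(system) else NA_character_

  ids <- c("mother", "father",
           if (n_daughters > 0L) paste0("d", seq_len(n_daughters)),
           if (n_sons > 0L) paste0("s", seq_len(n_sons)))
  individuals <- data.frame(
    id = ids,
    role = c("mother", "father", rep("offspring", n_daughters + n_sons)),
    sex = c("F", "M", rep("F", n_daughters), rep("M", n_sons)),
    stringsAsFactors = FALSE)
  n_ind <- length(ids)
  n_off <- n_daughters + n_sons
  is_daughter <- c(rep(FALSE, 2L), rep(TRUE, n_daughters), rep(FALSE, n_sons))
  is_son <- c(rep(FALSE, 2L), rep(FALSE, n_daughters), rep(TRUE, n_sons))

  locus_class <- c(rep("autosomal", n_autosomal),
                   paste0(classes, "_linked", recycle0 = TRUE))
  n_loci <- length(locus_class)
  geno <- matrix(NA_character_, n_loci, n_ind,
                 dimnames = list(sprintf("tag%05d", seq_len(n_loci)), ids))
  if (n_loci > 0L) {
    # two distinct alleles per locus
    first <- sample.int(4L, n_loci, replace = TRUE)
    second <- sample.int(3L, n_loci, replace = TRUE)
    second <- second + (second >= first)
    a <- cbind(VALID_ALLELES[first], VALID_ALLELES[second])
    auto <- locus_class == "autosomal"
    if (any(auto))
      geno[auto, ] <- simulate_autosomal(a[auto, , drop = FALSE], n_off)
    link <- which(!auto)
    for (i in link)
      geno[i, ] <- simulate_sexlinked(a[i, ], locus_class[i],
                                      is_daughter, is_son)
  }
  truth <- list(loci = data.frame(locus_id = rownames(geno),
                                  class = locus_class, row.names = NULL,
                                  stringsAsFactors = FALSE),
                geno_true = geno)
  parent_cols <- 1:2
  off_cols <- setdiff(seq_len(n_ind), parent_cols)
  geno[, off_cols] <- apply_undercall(geno[, off_cols, drop = FALSE],
                                      undercall_rate)
  geno[, parent_cols] <- apply_undercall(geno[, parent_cols, drop = FALSE],
                                         undercall_rate * parent_error_scale)
  geno[, off_cols] <- apply_missing(geno[, off_cols, drop = FALSE],
                                    missing_rate)
  geno[, parent_cols] <- apply_missing(geno[, parent_cols, drop = FALSE],
                                       missing_rate * parent_error_scale)
  list(dataset = family_dataset(geno, individuals), truth = truth)
}

expand_sexlinked_classes <- function(n_sexlinked, system) {
  if (sum(n_sexlinked) == 0L) return(character())
  if (length(system) != 1L || !system %in% c("ZW", "XY"))
    stop("config error: n_sexlinked > 0 requires system = \"ZW\" or \"XY\"")
  allowed <- if (system == "ZW") c("W", "Z") else c("Y", "X")
  if (is.null(names(n_sexlinked))) {
    cls <- rep(allowed[1L], n_sexlinked)
  } else {
    if (!all(names(n_sexlinked) %in% allowed))
      stop("config error: sex-linked classes ",
           paste(setdiff(names(n_sexlinked), allowed), collapse = ","),
           " are not possible under a ", system, " system")
    cls <- rep(names(n_sexlinked), n_sexlinked)
  }
  cls
}

# Parent-pair genotype configurations over alleles (a, b) that leave the
# locus polymorphic in the family; offspring drawn by independent gamete
# sampling.  Vectorized over loci.  Returns a loci x individuals matrix.
simulate_autosomal <- function(alleles, n_off) {
  n <- nrow(alleles)
  # genotype codes 1 = a/a, 2 = a/b, 3 = b/b; drop the two monomorphic
  # crosses a/a x a/a and b/b x b/b, leaving 7 ordered configurations
  cfg <- expand.grid(mother = 1:3, father = 1:3)
  cfg <- cfg[!(cfg$mother == cfg$father & cfg$mother != 2L), ]
  k <- sample.int(nrow(cfg), n, replace = TRUE)
  mcode <- cfg$mother[k]
  fcode <- cfg$father[k]
  geno_of <- function(code)
    gt(alleles[cbind(seq_len(n), ifelse(code == 3L, 2L, 1L))],
       alleles[cbind(seq_len(n), ifelse(code == 1L, 1L, 2L))])
  gametes <- function(code) {
    # n x n_off matrix of transmitted alleles
    idx <- matrix(ifelse(code == 3L, 2L, 1L), n, n_off)
    het <- code == 2L
    if (any(het) && n_off > 0L)
      idx[het, ] <- sample.int(2L, sum(het) * n_off, replace = TRUE)
    matrix(alleles[cbind(rep(seq_len(n), n_off), as.vector(idx))], n, n_off)
  }
  out <- cbind(geno_of(mcode), geno_of(fcode))
  if (n_off > 0L) {
    kid <- gt(gametes(mcode), gametes(fcode))
    out <- cbind(out, matrix(kid, n, n_off))
  }
  out
}

# Fully sex-linked locus (no recombination).  The variant allele b rides on
# the sex-limited chromosome (W or Y) or on the heterogametic parent's
# shared chromosome (Z or X); the other parent is homozygous a/a.
simulate_sexlinked <- function(a, class, is_daughter, is_son) {
  ref <- a[1L]; var <- a[2L]
  n_ind <- length(is_daughter)
  out <- rep(gt(ref, ref), n_ind)
  het <- gt(ref, var)
  het_parent_col <- if (class %in% c("W_linked", "Z_linked")) 1L else 2L
  out[het_parent_col] <- het
  het_offspring <- switch(class,
                          W_linked = is_daughter, Z_linked = is_son,
                          Y_linked = is_son, X_linked = is_daughter)
  out[het_offspring] <- het
  out
}

#' Apply heterozygote undercalling to a genotype matrix
#'
#' Each non-missing heterozygous call independently becomes one of its two
#' homozygotes (equal probability) with probability `rate`.  Draws come from
#' the current RNG stream.
#'
#' @param geno character genotype matrix.
#' @param rate dropout probability per heterozygous call.
#' @return the perturbed matrix.
#' @export
apply_undercall <- function(geno, rate) {
  if (rate <= 0 || length(geno) == 0L) return(geno)
  het <- which(!is.na(geno) & as.vector(is_het(geno)))
  if (!length(het)) return(geno)
  hit <- het[stats::runif(length(het)) < rate]
  if (!length(hit)) return(geno)
  keep_first <- stats::runif(length(hit)) < 0.5
  al <- ifelse(keep_first, gt_allele(geno[hit], 1L), gt_allele(geno[hit], 2L))
  geno[hit] <- gt(al, al)
  geno
}

#' Apply random missingness to a genotype matrix
#'
#' @inheritParams apply_undercall
#' @param rate probability each call becomes missing.
#' @export
apply_missing <- function(geno, rate) {
  if (rate <= 0 || length(geno) == 0L) return(geno)
  drop <- !is.na(geno) & stats::runif(length(geno)) < rate
  geno[drop] <- NA_character_
  geno
}
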