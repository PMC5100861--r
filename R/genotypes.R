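#' Normalize diploid genotype strings
#'
#' Genotypes are represented throughout the package as unordered, unphased
#' diploid allele pairs written `"A/T"`, with the two allele symbols sorted so
#' that `"T/A"` and `"A/T"` are the same genotype.  Missing genotypes are `NA`.
#'
#' @param a,b single-character allele symbols (vectors recycle).
#' @return character vector of normalized genotype strings.
#' @examples
#' gt("T", "A")  # "A/T"
#' @export
gt <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "/")
}

#' @rdname gt
#' @param x character vector (or matrix) of genotype tokens like `"T/A"`.
#' @export
normalize_gt <- function(x) {
  if (length(x) == 0L) return(x)
  d <- dim(x)
  a1 <- substr(x, 1L, 1L)
  a2 <- substr(x, 3L, 3L)
  out <- ifelse(is.na(x), NA_character_, gt(a1, a2))
  dim(out) <- d
  dimnames(out) <- dimnames(x)
  out
}

# First/second allele of "A/T" tokens; preserves dim for matrices.
gt_allele <- function(x, which = 1L) {
  d <- dim(x)
  out <- substr(x, if (which == 1L) 1L else 3L, if (which == 1L) 1L else 3L)
  out[is.na(x)] <- NA_character_
  dim(out) <- d
  out
}

#' Test heterozygosity of genotype strings
#'
#' @param x character vector or matrix of normalized genotypes (`NA` allowed).
#' @return logical of the same shape; `NA` where the genotype is missing.
#' @export
is_het <- function(x) {
  out <- gt_allele(x, 1L) != gt_allele(x, 2L)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

VALID_ALLELES <- c("A", "C", "G", "T")
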