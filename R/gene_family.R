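#' Species-tagged gene-family alignment
#'
#' Container for one gene family: a set of equal-length aligned sequences
#' whose names encode the source species, an optional gene tree, and the
#' filtering state (status, rejection reason, ortholog partition).
#'
#' @param seqs named character vector of aligned sequences (equal lengths;
#'   `-` is the gap character).
#' @param tree optional `ape` phylo whose tip labels match `names(seqs)`.
#' @param delimiter character separating the species label from the copy id
#'   in sequence names (default `"|"`): `xlae|c1` is species `xlae`.
#' @param id optional family identifier.
#' @return an object of class `gene_family`: list with `seqs`, `species`
#'   (named vector), `tree`, `id`, `status` (`unassessed`/`accepted`/
#'   `rejected`), `rejection_reason` and `partition` (two ortholog sets when
#'   accepted).
#' @export
gene_family <- function(seqs, tree = NULL, delimiter = "|", id = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  len <- nchar(seqs)
  if (length(unique(len)) > 1L)
    stop("ragged alignment: sequence lengths ",
         paste(unique(len), collapse = ", "))
  species <- vapply(strsplit(names(seqs), delimiter, fixed = TRUE),
                    `[[`, "", 1L)
  if (any(!nzchar(species)) || any(species == names(seqs) & grepl(
        delimiter, names(seqs), fixed = TRUE)))
    stop("unparseable species label in sequence names")
  names(species) <- names(seqs)
  if (!is.null(tree) && !setequal(tree$tip.label, names(seqs)))
    stop("tree tips do not match sequence names")
  structure(list(seqs = seqs, species = species, tree = tree, id = id,
                 status = "unassessed", rejection_reason = NA_character_,
                 partition = NULL),
            class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  cat("gene_family", if (!is.null(x$id)) x$id else "", ":",
      length(x$seqs), "sequences x", nchar(x$seqs[[1L]]), "bp,",
      length(unique(x$species)), "species;", "status:", x$status, "\n")
  if (x$status == "accepted")
    cat("  partition: {", paste(x$partition[[1L]], collapse = ","), "} | {",
        paste(x$partition[[2L]], collapse = ","), "}\n")
  if (x$status == "rejected")
    cat("  reason:", x$rejection_reason, "\n")
  invisible(x)
}

# Ungapped length of one sequence (non-gap characters).
ungapped_nchar <- function(seq) nchar(gsub("-", "", seq))

# Number of alignment columns free of gaps in every sequence.
ungapped_columns <- function(seqs) {
  if (length(seqs) == 0L) return(0L)
  m <- do.call(rbind, strsplit(seqs, ""))
  sum(colSums(m == "-") == 0L)
}

# Pairwise p-distances with pairwise deletion of gap columns; ordered by
# sequence name for determinism.  Errors if a pair shares no comparable
# columns.
p_distance_matrix <- function(seqs) {
  seqs <- seqs[order(names(seqs))]
  m <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(m) <- names(seqs)
  dna <- ape::as.DNAbin(m)
  d <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) {
    bad <- which(!is.finite(dm), arr.ind = TRUE)[1L, ]
    stop("no comparable (gap-free in both) columns between ",
         rownames(dm)[bad[1L]], " and ", colnames(dm)[bad[2L]])
  }
  dm
}
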