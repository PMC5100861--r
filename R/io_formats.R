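#' Load a family genotype dataset from disk
#'
#' Reads a genotype file (VCF with `GT` calls, or the package's simple TSV
#' dialect) together with a pedigree table, validates both, and returns a
#' [family_dataset()].  Individuals are ordered as in the pedigree file.
#'
#' @param genotype_path path to a VCF (`.vcf`, uncompressed or gzipped) or a
#'   genotype TSV.  The TSV dialect has a header line
#'   `locus_id<TAB>id1<TAB>id2...` and one row per locus with genotype tokens
#'   like `A/T`; `./.` (or `.`) is missing.
#' @param pedigree_path path to a TSV with header columns `id`, `role`
#'   (`mother`/`father`/`offspring`) and `sex` (`F`/`M`/`U`).
#' @return a `family_dataset`.  Records with more than two alleles are kept
#'   and flagged in `$loci$multiallelic`.
#' @details VCF handling: only the `GT` field is consumed; `/` and `|`
#'   separators are both accepted and the pair is treated as unordered; any
#'   half-call or no-call (a `.` on either side) becomes missing.  Locus ids
#'   are the VCF `ID` when present, else `CHROM_POS`.
#' @seealso [write_family_dataset()]
#' @export
load_family_dataset <- function(genotype_path, pedigree_path) {
  ped <- load_pedigree(pedigree_path)
  if (is_vcf(genotype_path)) {
    g <- read_genotypes_vcf(genotype_path)
  } else {
    g <- read_genotypes_tsv(genotype_path)
  }
  if (!setequal(colnames(g), ped$id))
    stop("reconciliation error: sample ids differ between genotype file and ",
         "pedigree (only in genotypes: ",
         paste(setdiff(colnames(g), ped$id), collapse = ","),
         "; only in pedigree: ",
         paste(setdiff(ped$id, colnames(g)), collapse = ","), ")")
  family_dataset(g[, ped$id, drop = FALSE], ped)
}

load_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("id", "role", "sex") %in% names(ped)))
    stop("pedigree error: ", path, " must have columns id, role, sex")
  ped[, c("id", "role", "sex")]
}

is_vcf <- function(path) {
  first <- readLines(path, n = 1L)
  grepl("^##fileformat=VCF", first)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  ids <- fix[, "ID"]
  auto <- paste(fix[, "CHROM"], fix[, "POS"], sep = "_")
  ids <- ifelse(is.na(ids) | ids == ".", auto, ids)
  gt_num <- vcfR::extract.gt(v, element = "GT")
  alleles <- cbind(fix[, "REF"],
                   do.call(rbind, lapply(strsplit(fix[, "ALT"], ","),
                                         function(a) a[seq_len(3)])))
  out <- matrix(NA_character_, nrow = nrow(gt_num), ncol = ncol(gt_num),
                dimnames = list(ids, colnames(gt_num)))
  tok <- gsub("\\|", "/", gt_num)
  parts <- strsplit(tok, "/", fixed = TRUE)
  ok <- lengths(parts) == 2L
  i1 <- vapply(parts, function(p) p[1L], "")
  i2 <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else ".", "")
  full <- ok & i1 != "." & i2 != "." & !is.na(tok)
  full[is.na(full)] <- FALSE
  row_i <- row(gt_num)[full]
  a1 <- alleles[cbind(row_i, as.integer(i1[full]) + 1L)]
  a2 <- alleles[cbind(row_i, as.integer(i2[full]) + 1L)]
  out[full] <- gt(a1, a2)
  out
}

read_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("parse error: empty genotype file ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  ids <- header[-1L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  out <- matrix(NA_character_, nrow = length(body), ncol = length(ids),
                dimnames = list(NULL, ids))
  locus_ids <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(ids) + 1L)
      stop("parse error at line ", i + 1L, ": expected ", length(ids) + 1L,
           " fields, found ", length(f))
    locus_ids[i] <- f[1L]
    tok <- f[-1L]
    miss <- tok %in% c("./.", ".", "NA", "")
    bad <- !miss & !grepl("^[ACGT]/[ACGT]$", tok)
    if (any(bad))
      stop("parse error at line ", i + 1L, ": malformed genotype token '",
           tok[bad][1L], "'")
    out[i, !miss] <- tok[!miss]
  }
  rownames(out) <- locus_ids
  out
}

#' Write a family dataset as genotype + pedigree TSV
#'
#' Writes the TSV dialect read by [load_family_dataset()]; the round trip
#' reproduces genotypes and missingness exactly.
#'
#' @param x a `family_dataset`.
#' @param genotype_path,pedigree_path output paths.
#' @return `x`, invisibly.
#' @export
write_family_dataset <- function(x, genotype_path, pedigree_path = NULL) {
  g <- x$geno
  g[is.na(g)] <- "./."
  lines <- c(paste(c("locus_id", colnames(g)), collapse = "\t"),
             paste(rownames(g), apply(g, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, genotype_path)
  if (!is.null(pedigree_path))
    utils::write.table(x$individuals, pedigree_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Load a species-tagged gene-family alignment
#'
#' Reads a FASTA alignment (and optionally a Newick gene tree) into a
#' [gene_family()].  Sequence names encode the species with a delimiter,
#' e.g. `xlae|c1` is copy `c1` from species `xlae`.
#'
#' @param alignment_path FASTA file; all sequences must be the same length.
#' @param tree_path optional Newick file whose tip labels match the FASTA
#'   names exactly.
#' @param delimiter the character separating species label from copy id in
#'   sequence names (default `"|"`).
#' @return a `gene_family`.
#' @export
load_gene_family <- function(alignment_path, tree_path = NULL,
                             delimiter = "|") {
  dna <- ape::read.FASTA(alignment_path)
  if (length(dna) == 0L) stop("empty alignment: ", alignment_path)
  seqs <- vapply(as.character(dna), function(s) toupper(paste(s, collapse = "")), "")
  tree <- NULL
  if (!is.null(tree_path)) {
    tree <- ape::read.tree(tree_path)
    if (!setequal(tree$tip.label, names(seqs)))
      stop("tip/sequence name mismatch between ", tree_path, " and ",
           alignment_path, " (e.g. ",
           paste(utils::head(c(setdiff(tree$tip.label, names(seqs)),
                               setdiff(names(seqs), tree$tip.label)), 3L),
                 collapse = ","), ")")
  }
  gene_family(seqs, tree = tree, delimiter = delimiter)
}

#' Load a 12-column tabular homology hit file
#'
#' Parses the standard tabular hit format (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score; coordinates 1-based inclusive).
#'
#' @param path tab-separated hit file; an empty file yields an empty table.
#' @return a data frame of class `tag_hits`, one row per hit, grouped by
#'   query; e-values parsed as doubles (scientific notation supported).
#' @export
load_hit_table <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatches", "gapopens",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(matrix(nrow = 0L, ncol = 12L,
                                dimnames = list(NULL, cols)))
    out$query <- character(); out$subject <- character()
    class(out) <- c("tag_hits", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("parse error at line ", which(nf != 12L)[1L], ": expected 12 ",
         "tab-separated columns, found ", nf[nf != 12L][1L])
  m <- do.call(rbind, fields)
  out <- data.frame(query = m[, 1L], subject = m[, 2L],
                    pident = as.numeric(m[, 3L]),
                    length = as.integer(m[, 4L]),
                    mismatches = as.integer(m[, 5L]),
                    gapopens = as.integer(m[, 6L]),
                    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
                    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
                    evalue = as.numeric(m[, 11L]),
                    bitscore = as.numeric(m[, 12L]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$evalue))
    stop("parse error: unparseable e-value at line ",
         which(is.na(out$evalue))[1L])
  out <- out[order(match(out$query, unique(out$query))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tag_hits", "data.frame")
  out
}

#' Load a scaffold-to-chromosome alignment segment table
#'
#' @param path TSV with header columns `scaffold`, `chromosome`, `aln_start`,
#'   `aln_end` (half-open segment coordinates on the scaffold, `start < end`).
#' @return data frame with those columns plus `span = aln_end - aln_start`.
#' @export
load_scaffold_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("scaffold", "chromosome", "aln_start", "aln_end")
  if (!all(req %in% names(m)))
    stop("scaffold map must have columns ", paste(req, collapse = ", "))
  if (any(m$aln_start >= m$aln_end))
    stop("degenerate segment (start >= end) at row ",
         which(m$aln_start >= m$aln_end)[1L])
  m$span <- m$aln_end - m$aln_start
  m
}
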