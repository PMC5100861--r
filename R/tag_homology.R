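#' Classify tags by their homology-hit pattern
#'
#' Each query tag's hits are thresholded on e-value (strictly below
#' `evalue_threshold`) and the surviving distinct subject scaffolds counted.
#' One scaffold is scenario `one_region` (the scaffold is retained); two is
#' `two_regions` — typical of a short tag matching both homeologs of an
#' allotetraploid reference with similar strength — and one of the two
#' scaffolds is retained by a seeded random choice; more than two is
#' `multiple_regions` and zero is `no_region`, both of which discard the
#' tag.  Multiple HSPs on one scaffold count as one region.
#'
#' @param hits a `tag_hits` table from [load_hit_table()].
#' @param evalue_threshold hits with e-value at or above this are ignored
#'   (default `1e-5`).
#' @param seed optional seed for the two-region retention draw.
#' @return data frame with one row per query: `query`, `scenario`,
#'   `n_scaffolds` (distinct sub-threshold scaffolds) and
#'   `retained_scaffold` (`NA` for discarded tags).
#' @export
classify_tag_hits <- function(hits, evalue_threshold = 1e-5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  queries <- unique(hits$query)
  kept <- hits[hits$evalue < evalue_threshold, , drop = FALSE]
  scenario <- character(length(queries))
  retained <- rep(NA_character_, length(queries))
  n_scaf <- integer(length(queries))
  for (i in seq_along(queries)) {
    scafs <- sort(unique(kept$subject[kept$query == queries[i]]))
    n_scaf[i] <- length(scafs)
    if (length(scafs) == 0L) {
      scenario[i] <- "no_region"
    } else if (length(scafs) == 1L) {
      scenario[i] <- "one_region"
      retained[i] <- scafs
    } else if (length(scafs) == 2L) {
      scenario[i] <- "two_regions"
      retained[i] <- sample(scafs, 1L)
    } else {
      scenario[i] <- "multiple_regions"
    }
  }
  data.frame(query = queries, scenario = scenario, n_scaffolds = n_scaf,
             retained_scaffold = retained, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assign a scaffold to a chromosome via alignment segments
#'
#' Uses a scaffold-to-chromosome alignment segment table (e.g. from a
#' whole-genome aligner) to place a scaffold.  Segments all on one
#' chromosome give that chromosome; segments on exactly two chromosomes,
#' each with at least `min_span` aligned bases, give a split assignment; a
#' scaffold absent from the map is unplaced, as is one whose substantial
#' alignments hit three or more chromosomes.
#'
#' @param scaffold scaffold id.
#' @param map segment table from [load_scaffold_map()].
#' @param min_span minimum aligned bases per chromosome for a chromosome to
#'   count toward a split call (default 1000).
#' @return list with `status` (`"single"`, `"split"` or `"unplaced"`) and
#'   `chromosomes` (length 1, 2 or 0; split chromosomes sorted).
#' @export
assign_chromosome <- function(scaffold, map, min_span = 1000L) {
  seg <- map[map$scaffold == scaffold, , drop = FALSE]
  if (nrow(seg) == 0L)
    return(list(status = "unplaced", chromosomes = character()))
  chroms <- unique(seg$chromosome)
  if (length(chroms) == 1L)
    return(list(status = "single", chromosomes = chroms))
  spans <- tapply(seg$span, seg$chromosome, sum)
  major <- names(spans)[spans >= min_span]
  if (length(major) == 1L)
    return(list(status = "single", chromosomes = major))
  if (length(major) == 2L)
    return(list(status = "split", chromosomes = sort(major)))
  list(status = "unplaced", chromosomes = character())
}

#' Map retained tags to chromosomes
#'
#' Applies [assign_chromosome()] to the retained scaffold of each
#' non-discarded tag from [classify_tag_hits()].
#'
#' @param classified output of [classify_tag_hits()].
#' @param map segment table from [load_scaffold_map()].
#' @param min_span passed to [assign_chromosome()].
#' @return `classified` with added columns `placement` (`single`/`split`/
#'   `unplaced`/`NA` for discarded tags) and `chromosome` (the chromosome,
#'   or `"A+B"` for splits).
#' @export
assign_tags <- function(classified, map, min_span = 1000L) {
  classified$placement <- rep(NA_character_, nrow(classified))
  classified$chromosome <- rep(NA_character_, nrow(classified))
  has_scaf <- !is.na(classified$retained_scaffold)
  for (i in which(has_scaf)) {
    a <- assign_chromosome(classified$retained_scaffold[i], map, min_span)
    classified$placement[i] <- a$status
    classified$chromosome[i] <- if (a$status == "single") a$chromosomes
      else if (a$status == "split") paste(a$chromosomes, collapse = "+")
      else NA_character_
  }
  classified
}

#' Tally tag assignments per chromosome
#'
#' @param assigned output of [assign_tags()].
#' @return named integer vector: counts of retained tags per single
#'   chromosome (sorted by name), then `split`, then `unplaced`; empty input
#'   gives an empty vector.
#' @export
summarize_assignments <- function(assigned) {
  placed <- assigned[!is.na(assigned$placement), , drop = FALSE]
  if (nrow(placed) == 0L) return(stats::setNames(integer(), character()))
  singles <- placed$chromosome[placed$placement == "single"]
  tally <- table(singles)
  out <- c(stats::setNames(as.integer(tally), names(tally))[
             order(names(tally))],
           split = sum(placed$placement == "split"),
           unplaced = sum(placed$placement == "unplaced"))
  out[out > 0L | names(out) %in% names(tally)]
}
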