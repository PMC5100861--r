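#' Harmonic-mean marginal likelihood and Bayes factor
#'
#' Estimates each chain's marginal log-likelihood by the harmonic-mean
#' estimator over post-burn-in log-likelihood samples, computed stably in
#' log space: `lnML = log(n) - logsumexp(-l_i)`.  The comparison is reported
#' on the `2 ln BF` scale of Kass and Raftery: values above ~2 are positive
#' evidence and above ~10 strong evidence for the first model.
#'
#' @param trace_a,trace_b numeric vectors of post-burn-in log-likelihood
#'   samples, one value per state, for the two competing models (e.g. a
#'   relaxed versus a strict molecular clock).
#' @return `2 * (lnML_a - lnML_b)`; positive favors model a.
#' @examples
#' harmonic_mean_bf(rep(-10, 50), rep(-12, 50))  # 4: constant traces
#' @export
harmonic_mean_bf <- function(trace_a, trace_b) {
  2 * (harmonic_mean_lnml(trace_a) - harmonic_mean_lnml(trace_b))
}

#' @rdname harmonic_mean_bf
#' @param trace numeric vector of log-likelihood samples.
#' @export
harmonic_mean_lnml <- function(trace) {
  if (length(trace) == 0L) stop("empty likelihood trace")
  if (any(!is.finite(trace))) stop("non-finite values in likelihood trace")
  log(length(trace)) - logsumexp(-trace)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Read a log-likelihood trace file
#'
#' @param path text file with one log-likelihood value per line (post
#'   burn-in by convention).
#' @return numeric vector.
#' @export
read_loglik_trace <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (length(x) == 0L) stop("empty likelihood trace: ", path)
  x
}

#' Rescale a chronogram to a (drawn) root age
#'
#' Rescales all branch lengths of a rooted, ultrametric time tree so that
#' the root age equals a target: either an explicit `root_age`, or a draw
#' from a normal distribution (default mean 65 MY, SD 4.62 MY) truncated at
#' zero by rejection.  Relative node depths — and hence the topology and all
#' age ratios — are preserved exactly; only the time scale changes.  This is
#' the standard post-hoc dating of an uncalibrated posterior tree sample.
#'
#' @param tree a rooted `ape` phylo with branch lengths and positive
#'   root-to-tip depth.
#' @param root_age_mean,root_age_sd parameters (in MY) of the normal
#'   distribution the root age is drawn from (defaults 65 and 4.62).
#' @param root_age optional explicit root age; when given, no draw is made.
#' @param seed optional seed for the draw.
#' @param tol tolerance for the ultrametricity check (relative, default
#'   `1e-6`).
#' @return the rescaled phylo, with attribute `root_age` set to the target
#'   age used.
#' @export
rescale_chronogram <- function(tree, root_age_mean = 65, root_age_sd = 4.62,
                               root_age = NULL, seed = NULL, tol = 1e-6) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_along(tree$tip.label)]
  cur <- max(tip_depths)
  if (cur <= 0) stop("zero-depth tree cannot be rescaled")
  if (diff(range(tip_depths)) > tol * cur)
    warning("tree is not ultrametric within tolerance; rescaling anyway")
  if (is.null(root_age)) {
    if (!is.null(seed)) set.seed(seed)
    repeat {
      root_age <- stats::rnorm(1L, root_age_mean, root_age_sd)
      if (root_age > 0) break
    }
  }
  tree$edge.length <- tree$edge.length * (root_age / cur)
  attr(tree, "root_age") <- root_age
  tree
}

#' Node ages of a chronogram
#'
#' @param tree a rooted ultrametric phylo.
#' @return numeric vector of ages (time before present) for all nodes,
#'   tips first then internal nodes, in `ape`'s node numbering.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_along(tree$tip.label)]) - depths
}
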