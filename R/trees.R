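#' UPGMA clustering of a population distance matrix
#'
#' Standard unweighted pair-group agglomeration with arithmetic-mean cluster
#' distances; node heights are half the merge distance, so the tree is
#' ultrametric. Labels are sorted lexicographically before clustering so that
#' tie-breaking is deterministic.
#'
#' @param d Symmetric nonnegative matrix over population labels (or a
#'   `dist`).
#' @return A rooted ultrametric `ape::phylo` tree.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs labels")
  if (any(d < 0)) stop("negative distances; floor pairwise values first")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (nrow(d) < 2L) stop("need at least 2 labels")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  phy <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  phy
}

#' Consensus population tree from per-locus differentiation matrices
#'
#' Averages the per-locus pairwise matrices element-wise (pairs missing from
#' a locus are excluded from that pair's mean), floors negative entries at
#' zero, and builds the UPGMA tree.
#'
#' @param mats A list of labelled P x P matrices, or a `pairwise_diff` from
#'   [pairwise_matrix()].
#' @return A rooted ultrametric `ape::phylo` tree.
#' @export
consensus_tree <- function(mats) {
  if (inherits(mats, "pairwise_diff")) return(upgma(mats$consensus_floored))
  pops <- sort(unique(unlist(lapply(mats, rownames))))
  acc <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  cnt <- matrix(0L, length(pops), length(pops), dimnames = list(pops, pops))
  for (m in mats) {
    idx <- match(rownames(m), pops)
    ok <- !is.na(m)
    acc[idx, idx][ok] <- acc[idx, idx][ok] + m[ok]
    cnt[idx, idx][ok] <- cnt[idx, idx][ok] + 1L
  }
  mean_m <- acc / cnt
  diag(mean_m) <- 0
  if (any(is.na(mean_m)))
    stop("some population pairs have no data at any locus")
  upgma(pmax(mean_m, 0))
}

#' Test whether two trees share the same unrooted topology
#'
#' Compares the unrooted split (bipartition) sets; branch lengths and root
#' placement are ignored.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return `TRUE` if the unrooted topologies are identical.
#' @export
topology_equal <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf sets differ")
  n <- length(t1$tip.label)
  if (n <= 3L) return(TRUE)   # a single unrooted topology exists
  u1 <- ape::unroot(t1)
  u2 <- ape::unroot(t2)
  ape::dist.topo(u1, u2, method = "PH85") == 0
}
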