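# shared skeleton for the component distance matrices
.dist_mat <- function(m, labels, component, weight = NA_real_) {
  dimnames(m) <- list(labels, labels)
  attr(m, "component") <- component
  attr(m, "repeat_weight") <- weight
  m
}

# alleles usable for repeat-based distances
.perfect_idx <- function(dec) which(!dec$alleles$imperfect &
                                    !dec$alleles$degenerate)

#' Amplicon-size distance matrix
#'
#' Pairwise absolute difference in amplicon length (bp) — the scalar
#' Euclidean distance on fragment sizes.
#'
#' @param dec An [decompose_alleles()] result.
#' @return Symmetric matrix over alleles (attribute `component = "size"`).
#' @export
dist_amplicon_size <- function(dec) {
  s <- dec$alleles$amplicon_size
  .dist_mat(abs(outer(s, s, "-")), dec$alleles$sample_id, "size")
}

#' Repeat-count distance matrix
#'
#' Absolute difference in repeat number for a single block; Euclidean norm of
#' the per-block differences for compound repeats. Imperfect and degenerate
#' alleles are excluded (their repeat counts are not defined under a stepwise
#' model).
#'
#' @param dec An [decompose_alleles()] result.
#' @return Symmetric matrix over the retained (perfect) alleles.
#' @export
dist_ssr <- function(dec) {
  keep <- .perfect_idx(dec)
  reps <- dec$repeats[keep, , drop = FALSE]
  d2 <- matrix(0, length(keep), length(keep))
  for (b in seq_len(ncol(reps)))
    d2 <- d2 + outer(reps[, b], reps[, b], "-")^2
  .dist_mat(sqrt(d2), dec$alleles$sample_id[keep], "ssr")
}

# count of sites with differing states, pairwise-complete
.state_diff_matrix <- function(states) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  for (s in seq_len(ncol(states))) {
    x <- states[, s]
    neq <- outer(x, x, "!=")
    neq[is.na(neq)] <- FALSE
    d <- d + neq
  }
  d
}

#' Flanking-region distance matrix
#'
#' Number of flanking-region sites (SNPs, plus each indel run counted as a
#' single mutational event) at which two alleles differ. Sites where either
#' allele is missing (gap under an indel) are skipped pairwise.
#'
#' @param dec An [decompose_alleles()] result.
#' @return Symmetric matrix over alleles (`component = "fr"`).
#' @export
dist_fr <- function(dec) {
  .dist_mat(.state_diff_matrix(dec$fr_states), dec$alleles$sample_id, "fr")
}

#' Whole-amplicon sequence distance matrix
#'
#' Total number of mutational differences: flanking-region differing sites
#' plus `repeat_weight` times the summed absolute repeat-count differences
#' per block. Weight 1 gives the plain mutational-step count; 0.05 is the
#' down-weighting used when repeat steps enter a mutational-distance
#' differentiation analysis (repeats mutate much faster than flanking sites).
#' Imperfect/degenerate alleles are excluded (no defined repeat counts).
#'
#' @param dec An [decompose_alleles()] result.
#' @param repeat_weight Weight per repeat-count step (default 1).
#' @return Symmetric matrix over the retained alleles (`component = "full"`).
#' @export
dist_full <- function(dec, repeat_weight = 1) {
  keep <- .perfect_idx(dec)
  d <- .state_diff_matrix(dec$fr_states[keep, , drop = FALSE])
  reps <- dec$repeats[keep, , drop = FALSE]
  for (b in seq_len(ncol(reps)))
    d <- d + repeat_weight * abs(outer(reps[, b], reps[, b], "-"))
  .dist_mat(d, dec$alleles$sample_id[keep], "full", weight = repeat_weight)
}

#' Mantel test of association between two distance matrices
#'
#' Computes the cross-product statistic `Z = sum_{i<j} X_ij * Y_ij` and the
#' Pearson correlation `r` over the off-diagonal upper triangle, then permutes
#' the labels of one matrix jointly (rows and columns). The p-value is
#' one-tailed for positive association with the add-one rule:
#' `p = (1 + #{r_perm >= r_obs}) / (permutations + 1)`.
#'
#' @param X,Y Symmetric matrices with identical dimnames in the same order.
#' @param permutations Number of permutations (default 9999).
#' @param seed Optional RNG seed.
#' @return An object of class `mantel_result` (`Z`, `r`, `p`,
#'   `applicable = FALSE` with zero-variance input).
#' @export
mantel_test <- function(X, Y, permutations = 9999L, seed = NULL) {
  if (!identical(dim(X), dim(Y))) stop("matrix dimension mismatch")
  if (!is.null(rownames(X)) && !identical(rownames(X), rownames(Y)))
    stop("matrix labels differ")
  n <- nrow(X)
  if (n < 4L) stop("Mantel test needs at least 4 objects")
  ut <- upper.tri(X)
  x <- X[ut]; y <- Y[ut]
  Z <- sum(x * y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(Z = Z, r = NA_real_, p = NA_real_,
                          permutations = permutations, seed = seed,
                          applicable = FALSE,
                          reason = "zero variance in a matrix"),
                     class = "mantel_result"))
  r_obs <- stats::cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(permutations)) {
    p <- sample.int(n)
    yp <- Y[p, p][ut]
    if (stats::cor(x, yp) >= r_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(Z = Z, r = r_obs, p = (1 + hits) / (permutations + 1),
                 permutations = permutations, seed = seed,
                 applicable = TRUE, reason = NA_character_),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (!x$applicable) cat("Mantel test not applicable:", x$reason, "\n")
  else cat(sprintf("Mantel test: Z = %.4g, r = %.4f, p = %.4g (%d permutations)\n",
                   x$Z, x$r, x$p, x$permutations))
  invisible(x)
}

#' Concordance of the four component distance matrices
#'
#' Builds the size, repeat, flanking and whole-sequence distance matrices over
#' the common (perfect) allele set and Mantel-tests every unordered pair.
#'
#' @param dec An [decompose_alleles()] result.
#' @param permutations,seed Mantel settings.
#' @param alpha Significance level for the summary.
#' @param skip_ssr Skip the repeat component (e.g. extremely complex repeat
#'   structure).
#' @return An object of class `concordance_report`: data frame of pairwise
#'   results plus counts of significant pairs.
#' @export
concordance_report <- function(dec, permutations = 999L, seed = NULL,
                               alpha = 0.05, skip_ssr = FALSE) {
  keep <- .perfect_idx(dec)
  sub <- .subset_decomposition(dec, keep)
  mats <- list(size = dist_amplicon_size(sub),
               ssr = if (!skip_ssr) dist_ssr(sub),
               fr = dist_fr(sub),
               full = dist_full(sub, repeat_weight = 1))
  mats <- Filter(Negate(is.null), mats)
  comps <- names(mats)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_along(comps)[-length(comps)])
    for (j in (i + 1L):length(comps)) {
      mt <- mantel_test(mats[[i]], mats[[j]], permutations = permutations)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = dec$locus, component_a = comps[i], component_b = comps[j],
        Z = mt$Z, r = if (is.null(mt$r)) NA else mt$r, p = mt$p,
        class = ld_class(mt$p, alpha), applicable = mt$applicable,
        stringsAsFactors = FALSE)
    }
  tab <- do.call(rbind, rows)
  ok <- tab$applicable
  structure(list(pairs = tab, n_pairs = nrow(tab),
                 n_applicable = sum(ok),
                 n_significant = sum(tab$p[ok] <= alpha, na.rm = TRUE),
                 alpha = alpha, locus = dec$locus),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Distance-matrix concordance at '", x$locus, "': ", x$n_significant,
      " of ", x$n_pairs, " matrix pairs significantly correlated (alpha = ",
      x$alpha, ")\n", sep = "")
  invisible(x)
}
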