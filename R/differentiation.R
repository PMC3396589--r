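# Phi and variance components from a squared-distance matrix and a
# population index list. Core AMOVA algebra for haploid allele copies:
#   SSD_total  = (1/N)  sum_{i<j} d2_ij
#   SSD_within = sum_p (1/N_p) sum_{i<j in p} d2_ij
#   sigma2_w   = SSD_within / (N - P)
#   n'         = (N - sum N_p^2 / N) / (P - 1)
#   sigma2_a   = (SSD_among / (P - 1) - sigma2_w) / n'
#   Phi        = sigma2_a / (sigma2_a + sigma2_w)
.amova_phi <- function(d2, idx_by_pop) {
  N <- sum(lengths(idx_by_pop))
  P <- length(idx_by_pop)
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- 0
  for (idx in idx_by_pop) {
    sub <- d2[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - P)
  n_prime <- (N - sum(lengths(idx_by_pop)^2) / N) / (P - 1)
  sigma_a <- (ssd_among / (P - 1) - sigma_w) / n_prime
  phi <- if (sigma_a + sigma_w <= 0) 0 else sigma_a / (sigma_a + sigma_w)
  list(phi = phi, sigma_a = sigma_a, sigma_w = sigma_w,
       ssd_total = ssd_total, ssd_within = ssd_within,
       ssd_among = ssd_among, n_prime = n_prime, N = N, P = P)
}

#' Analysis of molecular variance (AMOVA) over haploid allele copies
#'
#' Partitions the squared-distance variation among alleles into among- and
#' within-population variance components and returns the fixation index
#' `Phi = sigma2_among / (sigma2_among + sigma2_within)`. Significance is
#' assessed by permuting alleles among populations.
#'
#' @param d2 Symmetric matrix of *squared* pairwise distances among allele
#'   copies (zero diagonal).
#' @param pops Population label per allele (character or factor, length
#'   `nrow(d2)`).
#' @param permutations Number of permutations (default 1000; 0 skips the
#'   test).
#' @param seed Optional RNG seed.
#' @param statistic Label recorded on the result (e.g. `"PhiST"`, `"FST"`).
#' @return An object of class `differentiation_result`.
#' @export
amova <- function(d2, pops, permutations = 1000L, seed = NULL,
                  statistic = "PhiST") {
  d2 <- as.matrix(d2)
  pops <- as.character(pops)
  stopifnot(nrow(d2) == length(pops))
  idx <- split(seq_along(pops), pops)
  if (any(lengths(idx) == 0L)) stop("empty population after filtering")
  if (length(idx) < 2L) stop("need at least 2 populations")
  obs <- .amova_phi(d2, idx)
  monomorphic <- obs$ssd_total == 0
  p <- NA_real_
  if (permutations > 0L && !monomorphic) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    n <- length(pops)
    for (b in seq_len(permutations)) {
      perm <- split(sample.int(n), pops)
      if (.amova_phi(d2, perm)$phi >= obs$phi - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (permutations + 1)
  }
  structure(list(statistic = statistic, value = obs$phi,
                 sigma_among = obs$sigma_a, sigma_within = obs$sigma_w,
                 ssd_among = obs$ssd_among, ssd_within = obs$ssd_within,
                 ssd_total = obs$ssd_total, n_prime = obs$n_prime,
                 df_among = obs$P - 1L, df_within = obs$N - obs$P,
                 n = obs$N, n_pops = obs$P, p = p,
                 permutations = permutations, seed = seed,
                 monomorphic = monomorphic, component = NA_character_,
                 repeat_weight = NA_real_),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(x$statistic,
      if (!is.na(x$component)) paste0(" (", x$component, ")") else "",
      " = ", signif(x$value, 4), sep = "")
  if (!is.na(x$p)) cat(", p = ", signif(x$p, 4),
                       " (", x$permutations, " permutations)", sep = "")
  if (x$monomorphic) cat(" [monomorphic]")
  cat("\n")
  cat(sprintf("  variance components: among = %.6g, within = %.6g\n",
              x$sigma_among, x$sigma_within))
  invisible(x)
}

# classification keys per component of variation
.component_classes <- function(dec, component) {
  al <- dec$alleles
  switch(component,
         size = as.character(al$amplicon_size),
         repeats = apply(dec$repeats, 1L, paste, collapse = ","),
         fr = al$fr_haplotype,
         full = al$seq_haplotype,
         stop("unknown component '", component, "'"))
}

# drop alleles without defined repeat counts for repeat-bearing components
.component_keep <- function(dec, component) {
  if (component %in% c("repeats", "full")) .perfect_idx(dec)
  else seq_len(nrow(dec$alleles))
}

#' Haplotype-level F\eqn{_{ST}} via AMOVA with identity distances
#'
#' Alleles are classified into discrete classes for the chosen component and
#' AMOVA is run with squared distance 0 for identical classes and 1
#' otherwise — the haplotype-frequency analogue of F\eqn{_{ST}} for haploid
#' allele copies. A data set with a single class returns 0 (flagged
#' monomorphic).
#'
#' @param dec An [decompose_alleles()] result (carries population labels).
#' @param component One of `"size"`, `"repeats"`, `"fr"`, `"full"`.
#' @param permutations,seed See [amova()].
#' @return A `differentiation_result` with `statistic = "FST"`.
#' @export
fst <- function(dec, component = c("full", "fr", "size", "repeats"),
                permutations = 1000L, seed = NULL) {
  component <- match.arg(component)
  keep <- .component_keep(dec, component)
  sub <- .subset_decomposition(dec, keep)
  cls <- .component_classes(sub, component)
  d2 <- 1 * outer(cls, cls, "!=")
  res <- amova(d2, sub$alleles$population, permutations, seed,
               statistic = "FST")
  res$component <- component
  res
}

#' R\eqn{_{ST}}: AMOVA on squared size or repeat-count differences
#'
#' The stepwise-mutation-model analogue: squared differences in amplicon size
#' (bp) or in repeat counts (summed over blocks for compound repeats) enter
#' the AMOVA as squared distances. Imperfect/degenerate alleles are excluded
#' when repeat counts are involved.
#'
#' @param dec An [decompose_alleles()] result.
#' @param on `"size"` or `"repeats"`.
#' @param permutations,seed See [amova()].
#' @return A `differentiation_result` with `statistic = "RST"`.
#' @export
rst <- function(dec, on = c("size", "repeats"), permutations = 1000L,
                seed = NULL) {
  on <- match.arg(on)
  keep <- if (on == "repeats") .perfect_idx(dec) else
    seq_len(nrow(dec$alleles))
  sub <- .subset_decomposition(dec, keep)
  d2 <- if (on == "size") {
    s <- sub$alleles$amplicon_size
    outer(s, s, "-")^2
  } else {
    d <- matrix(0, nrow(sub$alleles), nrow(sub$alleles))
    for (b in seq_len(ncol(sub$repeats)))
      d <- d + outer(sub$repeats[, b], sub$repeats[, b], "-")^2
    d
  }
  res <- amova(d2, sub$alleles$population, permutations, seed,
               statistic = "RST")
  res$component <- on
  res
}

#' N\eqn{_{ST}}: AMOVA on mutational-step distances
#'
#' Differentiation based on the number of mutational steps between allele
#' sequences: flanking-region differing sites, optionally plus repeat-count
#' steps down-weighted by `repeat_weight` (default 0.05, reflecting the much
#' faster repeat mutation rate) for the whole-amplicon variant. Step counts
#' enter the AMOVA as squared distances (the molecular-AMOVA convention);
#' set `square_steps = TRUE` to square them instead.
#'
#' @param dec An [decompose_alleles()] result.
#' @param component `"fr"` or `"full"`.
#' @param repeat_weight Weight per repeat step for `component = "full"`.
#' @param square_steps Square the step counts before AMOVA.
#' @param permutations,seed See [amova()].
#' @return A `differentiation_result` with `statistic = "NST"`.
#' @export
nst <- function(dec, component = c("fr", "full"), repeat_weight = 0.05,
                square_steps = FALSE, permutations = 1000L, seed = NULL) {
  component <- match.arg(component)
  if (component == "fr") {
    sub <- dec
    d <- dist_fr(dec)
  } else {
    keep <- .perfect_idx(dec)
    sub <- .subset_decomposition(dec, keep)
    d <- dist_full(sub, repeat_weight = repeat_weight)
  }
  d2 <- if (square_steps) d^2 else d
  res <- amova(unclass(d2), sub$alleles$population, permutations, seed,
               statistic = "NST")
  res$component <- component
  res$repeat_weight <- if (component == "full") repeat_weight else NA_real_
  res
}

#' Pairwise population differentiation matrices and multi-locus consensus
#'
#' Runs a two-population AMOVA for every population pair at every locus and
#' averages the per-locus matrices into a consensus (pairs monomorphic at a
#' locus are excluded from that pair's average). For tree building, negative
#' pairwise values are floored at zero in `consensus_floored`; raw values are
#' preserved.
#'
#' @param decs A list of [decompose_alleles()] results (one per locus) or a
#'   single one.
#' @param statistic `"fst"`, `"rst"` or `"nst"`.
#' @param component Component passed to the statistic function.
#' @param repeat_weight For `nst(component = "full")`.
#' @return A list of class `pairwise_diff`: `per_locus` (list of P x P
#'   matrices), `consensus`, `consensus_floored`, `populations`.
#' @export
pairwise_matrix <- function(decs, statistic = c("fst", "rst", "nst"),
                            component = "full", repeat_weight = 0.05) {
  statistic <- match.arg(statistic)
  if (inherits(decs, "allele_decomposition")) decs <- list(decs)
  pops <- sort(unique(unlist(lapply(decs, function(d) d$alleles$population))))
  if (length(pops) < 2L) stop("need at least 2 populations")
  stat_fun <- function(sub) {
    switch(statistic,
           fst = fst(sub, component, permutations = 0L),
           rst = rst(sub, component, permutations = 0L),
           nst = nst(sub, component, repeat_weight = repeat_weight,
                     permutations = 0L))
  }
  per_locus <- lapply(decs, function(dec) {
    m <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
    for (i in seq_along(pops)[-length(pops)])
      for (j in (i + 1L):length(pops)) {
        keep <- which(dec$alleles$population %in% pops[c(i, j)])
        if (length(unique(dec$alleles$population[keep])) < 2L) next
        sub <- .subset_decomposition(dec, keep)
        res <- tryCatch(stat_fun(sub), error = function(e) NULL)
        if (is.null(res) || res$monomorphic) next
        m[i, j] <- m[j, i] <- res$value
      }
    diag(m) <- 0
    m
  })
  names(per_locus) <- vapply(decs, function(d) d$locus, character(1))
  arr <- simplify2array(per_locus)
  consensus <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  floored <- pmax(consensus, 0)
  structure(list(per_locus = per_locus, consensus = consensus,
                 consensus_floored = floored, populations = pops,
                 statistic = statistic, component = component),
            class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, ...) {
  cat("Pairwise ", toupper(x$statistic), " (", x$component, "), consensus of ",
      length(x$per_locus), " locus/loci:\n", sep = "")
  print(round(x$consensus, 4))
  invisible(x)
}
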