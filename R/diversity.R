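#' Nei's gene diversity
#'
#' Probability that two allele copies drawn at random differ, computed from
#' class counts. The default applies the unbiased small-sample correction
#' `n/(n-1) * (1 - sum(p_i^2))`; with `unbiased = FALSE` the plug-in form
#' `1 - sum(p_i^2)` is returned.
#'
#' @param counts Vector of class counts (one entry per distinct allele or
#'   haplotype class).
#' @param unbiased Apply the `n/(n-1)` correction (default `TRUE`).
#' @return Diversity in `[0, 1]`.
#' @export
nei_diversity <- function(counts, unbiased = TRUE) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 allele copies")
  he <- 1 - sum((counts / n)^2)
  if (unbiased) he <- he * n / (n - 1)
  he
}

#' SNP density per 100 bp of flanking sequence
#'
#' @param n_snps Number of flanking SNPs.
#' @param fr_length Flanking sequence length in bp.
#' @return `100 * n_snps / fr_length`, rounded to 2 decimals.
#' @export
snp_density <- function(n_snps, fr_length) {
  if (any(fr_length <= 0)) stop("fr_length must be > 0")
  round(100 * n_snps / fr_length, 2)
}

#' Per-component diversity summary for one locus
#'
#' One row per component of variation: amplicon size classes, each repeat
#' block (perfect alleles only), flanking-region haplotypes (with SNP/indel
#' counts and SNP density), and whole-amplicon sequence haplotypes.
#'
#' @param dec An [decompose_alleles()] result.
#' @param unbiased Use the unbiased Nei estimator.
#' @return A data frame with columns `locus`, `component`, `A` (distinct
#'   alleles, size/repeat components), `h` (distinct haplotypes, sequence
#'   components), `He`, `n_snps`, `n_indels`, `fr_length_bp`, `snp_density`.
#' @export
summarize_locus <- function(dec, unbiased = TRUE) {
  al <- dec$alleles
  he <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(c(k = length(unique(x)), He = 0))
    c(k = length(unique(x)), He = nei_diversity(table(x), unbiased))
  }
  rows <- list()
  add <- function(component, k = NA, h = NA, He, n_snps = NA, n_indels = NA,
                  fr_len = NA, dens = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      locus = dec$locus, component = component, A = k, h = h, He = He,
      n_snps = n_snps, n_indels = n_indels, fr_length_bp = fr_len,
      snp_density = dens, stringsAsFactors = FALSE)

  s <- he(al$amplicon_size)
  add("size", k = s[["k"]], He = s[["He"]])
  keep <- !al$imperfect & !al$degenerate
  for (b in seq_len(ncol(dec$repeats))) {
    s <- he(dec$repeats[keep, b])
    add(paste0("repeat", b), k = s[["k"]], He = s[["He"]])
  }
  fr_tab <- dec$sites$table[!dec$sites$table$in_repeat, , drop = FALSE]
  s <- he(al$fr_haplotype)
  add("fr", h = s[["k"]], He = s[["He"]],
      n_snps = sum(fr_tab$kind == "snp"),
      n_indels = sum(fr_tab$kind == "indel"),
      fr_len = dec$fr_length,
      dens = snp_density(sum(fr_tab$kind == "snp"), dec$fr_length))
  s <- he(al$seq_haplotype)
  add("full", h = s[["k"]], He = s[["He"]])
  do.call(rbind, rows)
}
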