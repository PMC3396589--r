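# Independent brute-force AMOVA oracle: every sum written as an explicit
# double loop over allele pairs, no shared code with the package engine.
brute_amova <- function(d2, pops) {
  pops <- as.character(pops)
  N <- length(pops)
  upops <- unique(pops)
  P <- length(upops)
  ssd_total <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ssd_total <- ssd_total + d2[i, j]
  ssd_total <- ssd_total / N
  ssd_within <- 0
  for (p in upops) {
    idx <- which(pops == p)
    np <- length(idx)
    s <- 0
    if (np >= 2)
      for (a in 1:(np - 1)) for (b in (a + 1):np) s <- s + d2[idx[a], idx[b]]
    ssd_within <- ssd_within + s / np
  }
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - P)
  np2 <- 0
  for (p in upops) np2 <- np2 + sum(pops == p)^2
  n_prime <- (N - np2 / N) / (P - 1)
  sigma_a <- (ssd_among / (P - 1) - sigma_w) / n_prime
  phi <- if (sigma_a + sigma_w <= 0) 0 else sigma_a / (sigma_a + sigma_w)
  list(phi = phi, sigma_a = sigma_a, sigma_w = sigma_w,
       ssd_total = ssd_total, ssd_within = ssd_within, ssd_among = ssd_among)
}

# random contingency table with >= 2 observed states on each side
random_ld_table <- function(max_n = 30, max_states = 3) {
  repeat {
    n <- sample(10:max_n, 1)
    a <- sample(sample(2:max_states, 1), n, replace = TRUE)
    b <- sample(sample(2:max_states, 1), n, replace = TRUE)
    tab <- table(a, b)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) >= 2 && ncol(tab) >= 2) return(unclass(unname(tab)))
  }
}

# alignment of n alleles whose flank carries exactly k biallelic SNP columns
# (no indels, no repeat variation)
make_snp_alignment <- function(k, n = 10, locus = "toy") {
  flank <- 2L * k + 10L
  base <- rep("A", flank)
  mat <- matrix(rep(base, each = n), n, flank)
  for (s in seq_len(k)) {
    carriers <- sample(seq_len(n), sample(2:(n - 2), 1))
    mat[carriers, 2L * s] <- "G"
  }
  block <- strsplit(strrep("GA", 8), "")[[1]]
  seqs <- apply(cbind(mat, matrix(rep(block, each = n), n)), 1,
                paste, collapse = "")
  names(seqs) <- paste0("al", seq_len(n))
  amplicon_alignment(locus, seqs,
                     stats::setNames(rep("pop1", n), names(seqs)),
                     data.frame(block = 1L, motif = "GA",
                                start = flank + 1L, end = flank + 16L))
}

# hand-built two-tip genealogy with both branches of length t
two_tip_tree <- function(t, labels = c("a", "b")) {
  phy <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                        edge.length = c(t, t), tip.label = labels,
                        Nnode = 1L), class = "phylo")
  phy$population <- stats::setNames(rep("P1", 2L), labels)
  phy
}

# small gapped alignment from explicit sequence strings (single GA block)
toy_alignment <- function(seqs, block_start, block_end, motif = "GA",
                          pops = NULL, locus = "toy") {
  if (is.null(pops)) pops <- stats::setNames(rep("pop1", length(seqs)),
                                             names(seqs))
  amplicon_alignment(locus, seqs, pops,
                     data.frame(block = 1L, motif = motif,
                                start = block_start, end = block_end))
}

# random AMOVA instance: continuous squared distances, 2-4 populations
random_amova_instance <- function(max_n = 20) {
  P <- sample(2:4, 1)
  np <- sample(2:5, P, replace = TRUE)
  while (sum(np) > max_n) np <- sample(2:5, P, replace = TRUE)
  x <- stats::rnorm(sum(np))
  list(d2 = outer(x, x, "-")^2,
       pops = rep(paste0("P", seq_len(P)), np))
}
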