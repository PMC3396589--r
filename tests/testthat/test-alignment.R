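test_that("construction validates shape and annotations", {
  seqs <- c(a = "ACGTGAGAGA", b = "ACGTGAGAGA", c = "ACTTGAGAGA",
            d = "ACGTGAGA--")
  blocks <- data.frame(block = 1L, motif = "GA", start = 5L, end = 10L)
  pops <- stats::setNames(rep("p1", 4), names(seqs))
  aln <- amplicon_alignment("L1", seqs, pops, blocks)
  expect_s3_class(aln, "amplicon_alignment")
  expect_identical(length(aln$ids), 4L)

  bad <- seqs; bad["c"] <- "ACTTGAGAG"      # 9 columns among 10
  expect_error(amplicon_alignment("L1", bad, pops, blocks), "ragged.*'c'")
  expect_error(amplicon_alignment("L1", seqs, pops,
                                  transform(blocks, end = 12L)),
               "exceeds consensus length")
  expect_error(amplicon_alignment("L1", seqs, pops,
                                  rbind(blocks,
                                        data.frame(block = 2L, motif = "CT",
                                                   start = 8L, end = 9L))),
               "disjoint")
})

test_that("file round-trip preserves the alignment", {
  cf <- sim_config(n_pops = 2, samples_per_pop = 4, effective_size = 300,
                   n_blocks = 2, motifs = c("GA", "CAT"),
                   init_repeats = c(8, 5), seed = 12)
  aln <- simulate_locus(cf)$alignment
  fa <- tempfile(fileext = ".fasta")
  an <- tempfile(fileext = ".tsv")
  pm <- tempfile(fileext = ".tsv")
  write_amplicon_alignment(aln, fa, an, pm)
  back <- read_amplicon_alignment(fa, an, pm)
  expect_identical(back$seqs, aln$seqs)
  expect_identical(back$blocks$motif, aln$blocks$motif)
  expect_identical(unname(back$populations), unname(aln$populations))
  expect_error(read_amplicon_alignment(fa, an, tempfile()), "not found")
})

test_that("samples missing from the popmap error unless explicitly allowed", {
  cf <- sim_config(n_pops = 1, samples_per_pop = 4, seed = 3)
  aln <- simulate_locus(cf)$alignment
  fa <- tempfile(fileext = ".fasta"); an <- tempfile(); pm <- tempfile()
  write_amplicon_alignment(aln, fa, an, pm)
  pmap <- utils::read.delim(pm)[-1, ]
  utils::write.table(pmap, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_amplicon_alignment(fa, an, pm), "missing from popmap")
  back <- read_amplicon_alignment(fa, an, pm, allow_unassigned = TRUE)
  expect_identical(unname(back$populations[1]), "unassigned")
})

test_that("a shared gap run is coded as one binary site whatever its length", {
  flank1 <- strrep("ACGT", 5)                       # cols 1..20
  run <- strrep("-", 12)                            # cols 21..32 in carriers
  keep <- "TGCATGCATGCA"
  flank2 <- strrep("AC", 5)                         # cols 33..42
  block <- strrep("GA", 6)
  with_run <- paste0(flank1, run, flank2, block)
  without <- paste0(flank1, keep, flank2, block)
  seqs <- c(al1 = with_run, al2 = with_run, al3 = with_run,
            stats::setNames(rep(without, 7), paste0("al", 4:10)))
  aln <- toy_alignment(seqs, block_start = 43L, block_end = 54L)
  sites <- call_sites(aln)
  idx <- sites$table$kind == "indel"
  expect_identical(sum(idx), 1L)
  expect_identical(sites$table$n_states[idx], 2L)
  expect_identical(sites$table$end[idx] - sites$table$start[idx] + 1L, 12L)
})

test_that("SNP sites carry all observed states; monomorphic columns none", {
  seqs <- c(al1 = "AAGTACGTACGAGA", al2 = "ACGTACGTACGAGA",
            al3 = "ATGTACGTACGAGA", al4 = "ACGTACGTACGAGA")
  # column 2 has states {A, C, T}; all other flank columns monomorphic
  aln <- toy_alignment(seqs, block_start = 11L, block_end = 14L)
  sites <- call_sites(aln)
  expect_identical(nrow(sites$table), 1L)
  expect_identical(sites$table$kind, "snp")
  expect_identical(sites$table$n_states, 3L)
  expect_setequal(unique(sites$states[, 1]), c("A", "C", "T"))
})

test_that("partially overlapping gap runs split into distinct binary sites", {
  #        cols 5-10 gapped in al1; cols 5-13 gapped in al2
  f <- function(gap_from, gap_to) {
    x <- strsplit("ACGTACGTACGTACGTACGT", "")[[1]]
    x[gap_from:gap_to] <- "-"
    paste(x, collapse = "")
  }
  seqs <- c(al1 = f(5, 10), al2 = f(5, 13),
            al3 = "ACGTACGTACGTACGTACGT", al4 = "ACGTACGTACGTACGTACGT")
  seqs <- vapply(seqs, function(s) paste0(s, "GAGAGA"), character(1))
  aln <- toy_alignment(seqs, block_start = 21L, block_end = 26L)
  sites <- call_sites(aln)
  ind <- sites$table[sites$table$kind == "indel", ]
  expect_identical(nrow(ind), 2L)                  # split at the boundary
  expect_identical(ind$start, c(5L, 11L))
  expect_true(all(ind$n_states == 2L))
})

test_that("decomposition recovers sizes, counts and flags imperfect repeats", {
  flank <- strrep("ACGTA", 10)                      # 50 bp each side
  perfect <- paste0(flank, strrep("GA", 10), flank)
  imperf <- paste0(flank, strrep("GA", 4), "GT", strrep("GA", 5), flank)
  seqs <- c(al1 = perfect, al2 = perfect, al3 = imperf)
  aln <- toy_alignment(seqs, block_start = 51L, block_end = 70L)
  dec <- decompose_alleles(aln)
  expect_identical(dec$alleles$amplicon_size, rep(120L, 3))
  expect_identical(unname(dec$repeats[, 1]), rep(10L, 3))
  expect_identical(dec$alleles$imperfect, c(FALSE, FALSE, TRUE))
  # imperfect allele keeps its size but leaves repeat-count analyses
  su <- summarize_locus(dec)
  expect_identical(su$A[su$component == "size"], 1)
  d <- dist_ssr(dec)
  expect_identical(rownames(d), c("al1", "al2"))
})

test_that("in-block length not divisible by the motif flags degenerate", {
  flank <- strrep("ACGTA", 4)
  ok <- paste0(flank, strrep("GAT", 4), flank)
  bad <- paste0(flank, strrep("GAT", 3), "GA-", flank)
  seqs <- c(al1 = ok, al2 = ok, al3 = bad)
  aln <- toy_alignment(seqs, block_start = 21L, block_end = 32L,
                       motif = "GAT")
  expect_warning(dec <- decompose_alleles(aln), "degenerate")
  expect_identical(dec$alleles$degenerate, c(FALSE, FALSE, TRUE))
})

test_that("homoplasy classes follow the i > ii > iii precedence", {
  flank <- strrep("ACGTA", 4)                       # 20 bp
  gap_flank <- paste0(substr(flank, 1, 4), "--", substr(flank, 7, 20))
  # class i: repeat counts 10 vs 11, the extra repeat offset by a 2-bp
  # flanking deletion, so amplicon sizes match (60 bp each)
  a1 <- paste0(flank, strrep("GA", 10), "--", flank)      # "--" = block pad
  a2 <- paste0(flank, strrep("GA", 11), gap_flank)
  aln <- toy_alignment(c(al1 = a1, al2 = a2), block_start = 21L,
                       block_end = 42L)
  rep_i <- detect_homoplasy(decompose_alleles(aln))
  expect_identical(rep_i$pairs$class, "i")
  expect_identical(rep_i$percent, 100)

  # class ii: compound blocks (10,5) vs (9,6), same total
  mk2 <- function(n1, n2) paste0(flank, strrep("GA", n1),
                                 strrep("-", 2 * (10 - n1)), flank,
                                 strrep("CT", n2),
                                 strrep("-", 2 * (6 - n2)), flank)
  aln2 <- amplicon_alignment(
    "two", c(al1 = mk2(10, 5), al2 = mk2(9, 6)),
    stats::setNames(rep("p", 2), c("al1", "al2")),
    data.frame(block = 1:2, motif = c("GA", "CT"),
               start = c(21L, 61L), end = c(40L, 72L)))
  rep_ii <- detect_homoplasy(decompose_alleles(aln2))
  expect_identical(rep_ii$pairs$class, "ii")

  # class iii: identical sizes and repeats, flanking SNP differs
  b1 <- paste0(flank, strrep("GA", 10), flank)
  b2 <- paste0(sub("^A", "T", flank), strrep("GA", 10), flank)
  aln3 <- toy_alignment(c(al1 = b1, al2 = b2), block_start = 21L,
                        block_end = 40L)
  rep_iii <- detect_homoplasy(decompose_alleles(aln3))
  expect_identical(rep_iii$pairs$class, "iii")
})

test_that("homoplasy percentage handles unique sizes and stays monotone", {
  flank <- strrep("ACGTA", 4)
  mk <- function(n) paste0(flank, strrep("GA", n), strrep("-", 2 * (12 - n)),
                           flank)
  seqs <- c(al1 = mk(8), al2 = mk(10), al3 = mk(12))
  aln <- toy_alignment(seqs, block_start = 21L, block_end = 44L)
  rep0 <- detect_homoplasy(decompose_alleles(aln))
  expect_identical(rep0$n_size_sharing, 0L)
  expect_true(is.na(rep0$percent))

  # adding an allele with a unique size never changes the numerator
  gap_flank <- paste0(substr(flank, 1, 4), "--", substr(flank, 7, 20))
  a1 <- paste0(flank, strrep("GA", 10), "--", flank)
  a2 <- paste0(flank, strrep("GA", 11), gap_flank)
  aln_pair <- toy_alignment(c(al1 = a1, al2 = a2), block_start = 21L,
                            block_end = 42L)
  n1 <- detect_homoplasy(decompose_alleles(aln_pair))$n_homoplasious
  a3 <- paste0(flank, strrep("GA", 5), strrep("-", 12), flank)
  aln_plus <- toy_alignment(c(al1 = a1, al2 = a2, al3 = a3),
                            block_start = 21L, block_end = 42L)
  n2 <- detect_homoplasy(decompose_alleles(aln_plus))$n_homoplasious
  expect_identical(n1, n2)
})
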