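test_that("variance components match the brute-force oracle", {
  set.seed(51)
  for (i in 1:20) {
    inst <- random_amova_instance()
    res <- amova(inst$d2, inst$pops, permutations = 0)
    bf <- brute_amova(inst$d2, inst$pops)
    expect_equal(res$value, bf$phi, tolerance = 1e-10)
    expect_equal(res$sigma_among, bf$sigma_a, tolerance = 1e-10)
    expect_equal(res$sigma_within, bf$sigma_w, tolerance = 1e-10)
    # SSD additivity holds exactly
    expect_equal(res$ssd_among + res$ssd_within, res$ssd_total,
                 tolerance = 1e-12)
  }
})

test_that("Phi is invariant to global scaling of squared distances", {
  set.seed(52)
  inst <- random_amova_instance()
  r1 <- amova(inst$d2, inst$pops, permutations = 0)
  r2 <- amova(7.3 * inst$d2, inst$pops, permutations = 0)
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
})

test_that("complete fixation gives Phi = 1 at the minimum attainable p", {
  d2 <- 1 - diag(8)
  d2[1:4, 1:4] <- 0; d2[5:8, 5:8] <- 0
  res <- amova(d2, rep(c("A", "B"), each = 4), permutations = 199, seed = 1)
  expect_equal(res$value, 1)
  # only label arrangements preserving the split reach Phi = 1
  expect_lte(res$p, 2 / choose(8, 4) + 0.05)
})

test_that("input validation: empty population and single population", {
  d2 <- matrix(0, 4, 4)
  expect_error(amova(d2, rep("A", 4)), "at least 2 populations")
})

test_that("FST on balanced class frequencies is near zero, fixed is one", {
  flank <- strrep("ACGTA", 4)
  mk <- function(n) paste0(flank, strrep("GA", n), strrep("-", 2 * (12 - n)),
                           flank)
  # both populations carry the same two haplotypes at equal frequency
  seqs <- stats::setNames(rep(c(mk(10), mk(12)), 4), paste0("al", 1:8))
  pops <- stats::setNames(rep(c("A", "B"), each = 4), names(seqs))
  dec <- decompose_alleles(toy_alignment(seqs, 21L, 44L, pops = pops))
  bal <- fst(dec, "full", permutations = 99, seed = 1)
  expect_lte(bal$value, 1e-9)
  expect_gt(bal$p, 0.05)
  # fixed difference
  seqs2 <- stats::setNames(rep(c(mk(10), mk(12)), each = 4),
                           paste0("al", 1:8))
  dec2 <- decompose_alleles(toy_alignment(seqs2, 21L, 44L, pops = pops))
  expect_equal(fst(dec2, "full", permutations = 0)$value, 1)
})

test_that("monomorphic data give FST 0 with the monomorphic flag", {
  flank <- strrep("ACGTA", 4)
  s <- paste0(flank, strrep("GA", 10), flank)
  seqs <- stats::setNames(rep(s, 6), paste0("al", 1:6))
  pops <- stats::setNames(rep(c("A", "B"), each = 3), names(seqs))
  dec <- decompose_alleles(toy_alignment(seqs, 21L, 40L, pops = pops))
  res <- fst(dec, "full", permutations = 99, seed = 1)
  expect_equal(res$value, 0)
  expect_true(res$monomorphic)
})

test_that("FST orders island-model migration rates correctly", {
  set.seed(53)
  wins <- 0L
  for (i in 1:40) {
    f <- function(m) {
      cf <- sim_config(n_pops = 2, samples_per_pop = 10,
                       effective_size = 500, mu_indel = 1e-5,
                       demography = list(kind = "island", migration_rate = m))
      dec <- decompose_alleles(simulate_locus(cf)$alignment)
      fst(dec, "full", permutations = 0)$value
    }
    if (f(2e-4) > f(2e-2)) wins <- wins + 1L
  }
  expect_gte(wins, 32L)   # >= 80% of paired replicates
})

test_that("RST is scale-equivalent between size and repeat views", {
  # invariant flanks, single block: size = const + 2 * repeats, so the
  # squared-distance matrices differ by a constant factor and Phi is equal
  flank <- strrep("ACGTA", 4)
  mk <- function(n) paste0(flank, strrep("GA", n), strrep("-", 2 * (14 - n)),
                           flank)
  set.seed(54)
  reps <- sample(8:14, 12, replace = TRUE)
  seqs <- stats::setNames(vapply(reps, mk, character(1)), paste0("al", 1:12))
  pops <- stats::setNames(rep(c("A", "B", "C"), each = 4), names(seqs))
  dec <- decompose_alleles(toy_alignment(seqs, 21L, 48L, pops = pops))
  expect_equal(rst(dec, "size", permutations = 0)$value,
               rst(dec, "repeats", permutations = 0)$value,
               tolerance = 1e-12)
})

test_that("RST mean under panmixia is near zero", {
  set.seed(55)
  vals <- replicate(400, {
    cf <- sim_config(n_pops = 1, samples_per_pop = 20, effective_size = 400)
    dec <- decompose_alleles(simulate_locus(cf)$alignment)
    dec$alleles$population <- rep(c("A", "B"), 10)   # arbitrary split
    rst(dec, "repeats", permutations = 0)$value
  })
  expect_lt(abs(mean(vals)), 2 * stats::sd(vals) / sqrt(length(vals)))
})

test_that("NST equals FST exactly when inter-class distances are constant", {
  flank <- strrep("ACGTA", 4)
  base <- paste0(flank, strrep("GA", 10), flank)
  alt <- paste0(sub("^AC", "TG", flank), strrep("GA", 10), flank)
  # two flanking haplotypes exactly 2 steps apart
  set.seed(56)
  seqs <- stats::setNames(sample(c(base, alt), 12, replace = TRUE),
                          paste0("al", 1:12))
  pops <- stats::setNames(rep(c("A", "B", "C"), each = 4), names(seqs))
  dec <- decompose_alleles(toy_alignment(seqs, 21L, 40L, pops = pops))
  expect_equal(nst(dec, "fr", permutations = 0)$value,
               fst(dec, "fr", permutations = 0)$value, tolerance = 1e-12)
})

test_that("weight zero collapses whole-amplicon NST onto flanking NST", {
  set.seed(57)
  cf <- sim_config(n_pops = 2, samples_per_pop = 8, effective_size = 600,
                   seed = 58)
  dec <- decompose_alleles(simulate_locus(cf)$alignment)
  expect_equal(nst(dec, "full", repeat_weight = 0, permutations = 0)$value,
               nst(dec, "fr", permutations = 0)$value, tolerance = 1e-12)
})

test_that("fixed flanking haplotypes three steps apart give NST 1", {
  flank <- strrep("ACGTA", 4)
  h1 <- paste0(flank, strrep("GA", 10), flank)
  h2 <- paste0(sub("^ACG", "TGC", flank), strrep("GA", 10), flank)
  seqs <- stats::setNames(rep(c(h1, h2), each = 4), paste0("al", 1:8))
  pops <- stats::setNames(rep(c("A", "B"), each = 4), names(seqs))
  dec <- decompose_alleles(toy_alignment(seqs, 21L, 40L, pops = pops))
  expect_equal(nst(dec, "fr", permutations = 0)$value, 1)
})

test_that("pairwise matrices cover all population pairs and average across loci", {
  set.seed(59)
  cf <- sim_config(n_pops = 4, samples_per_pop = 6, effective_size = 400,
                   mu_indel = 2e-5)
  decs <- lapply(simulate_dataset(cf, n_loci = 3, seed = 60),
                 function(s) decompose_alleles(s$alignment))
  pw <- pairwise_matrix(decs, "nst", "fr")
  expect_length(pw$per_locus, 3L)
  for (m in pw$per_locus) {
    expect_identical(dim(m), c(4L, 4L))
    expect_equal(sum(upper.tri(m) & !is.na(m)), 6)
  }
  manual <- (pw$per_locus[[1]] + pw$per_locus[[2]] + pw$per_locus[[3]]) / 3
  expect_equal(pw$consensus, manual, tolerance = 1e-12)
  expect_true(all(pw$consensus_floored >= 0))
})
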