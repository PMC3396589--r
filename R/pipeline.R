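#' Analysis configuration for the full pipeline
#'
#' Collects the inputs (either file paths or a simulation block) and the
#' statistical settings of every stage, with the conventional defaults:
#' repeat-step weight 0.05 for the weighted mutational-distance
#' differentiation, 1000 AMOVA permutations, 9999 Mantel permutations,
#' LD MCMC 10000 steps with 1000 burn-in, alpha 0.05.
#'
#' @param fasta,annotation,popmap Character vectors of input paths (one FASTA
#'   per locus; annotation/popmap may be single shared files). Ignored when
#'   `sim` is given.
#' @param sim A [sim_config()] to simulate the data instead of reading files.
#' @param n_loci Number of loci to simulate when `sim` is given.
#' @param repeat_weight Repeat-step weight for weighted NST.
#' @param amova_permutations,mantel_permutations,mcmc_steps,mcmc_burnin,alpha
#'   Stage settings.
#' @param seed Master seed; each random stage receives a seed derived from it.
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fasta = NULL, annotation = NULL, popmap = NULL,
                            sim = NULL, n_loci = 3L, repeat_weight = 0.05,
                            amova_permutations = 1000L,
                            mantel_permutations = 9999L,
                            mcmc_steps = 10000L, mcmc_burnin = 1000L,
                            alpha = 0.05, seed = 1L, out_dir = NULL) {
  if (is.null(sim) && is.null(fasta))
    stop("either input files (fasta/annotation/popmap) or a simulation ",
         "block must be given")
  structure(list(fasta = fasta, annotation = annotation, popmap = popmap,
                 sim = sim, n_loci = n_loci, repeat_weight = repeat_weight,
                 amova_permutations = amova_permutations,
                 mantel_permutations = mantel_permutations,
                 mcmc_steps = mcmc_steps, mcmc_burnin = mcmc_burnin,
                 alpha = alpha, seed = seed, out_dir = out_dir),
            class = "analysis_config")
}

# independent sub-seeds for each random stage (kept below 2^31)
.stage_seeds <- function(seed) {
  base <- as.integer(seed %% 1000000L)
  list(sim = base * 2L + 11L, ld = base * 2L + 101L,
       mantel = base * 2L + 211L, amova = base * 2L + 307L)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full amplicon analysis pipeline
#'
#' Executes decomposition, diversity summaries, linkage disequilibrium,
#' distance-matrix concordance, population differentiation and consensus
#' trees, and (when `out_dir` is set) writes the TSV/JSON/Newick report
#' bundle plus a manifest with checksums and the seeds used. Stages that need
#' multiple populations are skipped (with a note in the manifest) for
#' single-population data.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, the report bundle (a list with one entry per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seeds <- .stage_seeds(config$seed)

  # ---- inputs ----
  if (!is.null(config$sim)) {
    sims <- simulate_dataset(config$sim, n_loci = config$n_loci,
                             seed = seeds$sim)
    alns <- lapply(sims, `[[`, "alignment")
  } else {
    sims <- NULL
    ann <- rep_len(config$annotation, length(config$fasta))
    pm <- rep_len(config$popmap, length(config$fasta))
    alns <- Map(function(f, a, p) read_amplicon_alignment(f, a, p),
                config$fasta, ann, pm)
    names(alns) <- vapply(alns, `[[`, character(1), "locus")
  }

  # ---- decomposition, diversity, homoplasy ----
  decs <- lapply(alns, decompose_alleles)
  diversity <- do.call(rbind, lapply(decs, summarize_locus))
  rownames(diversity) <- NULL
  homoplasy <- lapply(decs, function(d)
    if (nrow(d$alleles) >= 2L) detect_homoplasy(d) else NULL)
  homoplasy <- Filter(Negate(is.null), homoplasy)
  n_sharing <- sum(vapply(homoplasy, `[[`, numeric(1), "n_size_sharing"))
  n_homo <- sum(vapply(homoplasy, `[[`, numeric(1), "n_homoplasious"))
  homoplasy_summary <- data.frame(
    n_size_sharing = n_sharing, n_homoplasious = n_homo,
    percent = if (n_sharing) round(100 * n_homo / n_sharing) else NA_real_)

  # ---- linkage disequilibrium ----
  lds <- lapply(decs, ld_matrix, steps = config$mcmc_steps,
                burnin = config$mcmc_burnin, alpha = config$alpha,
                seed = seeds$ld)
  ld_pairs <- do.call(rbind, lapply(lds, `[[`, "pairs"))
  rownames(ld_pairs) <- NULL
  ld_total <- sum(vapply(lds, `[[`, numeric(1), "n_pairs"))
  ld_sig <- sum(vapply(lds, `[[`, numeric(1), "n_significant"))
  ld_dist <- lapply(lds, ld_distance_mantel,
                    permutations = config$mantel_permutations,
                    seed = seeds$mantel)

  # ---- distance concordance ----
  conc <- lapply(decs, concordance_report,
                 permutations = config$mantel_permutations,
                 seed = seeds$mantel, alpha = config$alpha)
  mantel_pairs <- do.call(rbind, lapply(conc, `[[`, "pairs"))
  rownames(mantel_pairs) <- NULL

  # ---- differentiation + trees (needs >= 2 populations) ----
  n_pops <- length(unique(decs[[1L]]$alleles$population))
  diff_global <- NULL; pairwise <- NULL; trees <- NULL
  if (n_pops >= 2L) {
    runs <- list(
      list(fun = "fst", component = "size"),
      list(fun = "fst", component = "repeats"),
      list(fun = "fst", component = "fr"),
      list(fun = "fst", component = "full"),
      list(fun = "rst", component = "size"),
      list(fun = "rst", component = "repeats"),
      list(fun = "nst", component = "fr"),
      list(fun = "nst", component = "full"))
    rows <- list()
    for (dec in decs) for (rn in runs) {
      res <- tryCatch(switch(rn$fun,
        fst = fst(dec, rn$component, config$amova_permutations, seeds$amova),
        rst = rst(dec, rn$component, config$amova_permutations, seeds$amova),
        nst = nst(dec, rn$component, repeat_weight = config$repeat_weight,
                  permutations = config$amova_permutations,
                  seed = seeds$amova)),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        locus = dec$locus, statistic = res$statistic,
        component = res$component, value = res$value, p = res$p,
        sigma_among = res$sigma_among, sigma_within = res$sigma_within,
        stringsAsFactors = FALSE)
    }
    diff_global <- do.call(rbind, rows)
    rownames(diff_global) <- NULL
    pairwise <- list(
      fst = pairwise_matrix(decs, "fst", "full"),
      rst = pairwise_matrix(decs, "rst", "size"),
      nst = pairwise_matrix(decs, "nst", "full",
                            repeat_weight = config$repeat_weight))
    trees <- lapply(pairwise, function(pw)
      tryCatch(consensus_tree(pw), error = function(e) NULL))
  }

  bundle <- list(config = config, seeds = seeds, simulations = sims,
                 alignments = alns, decompositions = decs,
                 diversity = diversity, homoplasy = homoplasy,
                 homoplasy_summary = homoplasy_summary,
                 ld = lds, ld_pairs = ld_pairs,
                 ld_summary = data.frame(n_pairs = ld_total,
                                         n_significant = ld_sig,
                                         fraction = if (ld_total)
                                           ld_sig / ld_total else NA_real_),
                 ld_distance = ld_dist, concordance = conc,
                 mantel_pairs = mantel_pairs, diff_global = diff_global,
                 pairwise = pairwise, trees = trees)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

# write the report bundle; returns manifest
.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fp <- function(name) file.path(out_dir, name)
  files <- c(files, .write_tsv(make_table3(bundle), fp("table3.tsv")))
  for (dec in bundle$decompositions) {
    files <- c(files,
      .write_tsv(dec$alleles, fp(paste0("decomposition_", dec$locus, ".tsv"))),
      .write_tsv(dec$sites$table, fp(paste0("sites_", dec$locus, ".tsv"))))
  }
  files <- c(files, .write_tsv(bundle$ld_pairs, fp("ld_matrix.tsv")),
             .write_tsv(bundle$mantel_pairs, fp("mantel_pairs.tsv")),
             .write_tsv(bundle$homoplasy_summary, fp("homoplasy.tsv")))
  if (!is.null(bundle$diff_global))
    files <- c(files, .write_tsv(bundle$diff_global, fp("diff_global.tsv")))
  for (nm in names(bundle$pairwise)) {
    m <- bundle$pairwise[[nm]]$consensus
    df <- data.frame(population = rownames(m), m, check.names = FALSE)
    files <- c(files, .write_tsv(df, fp(paste0("diff_pairwise_", nm, ".tsv"))))
    tr <- bundle$trees[[nm]]
    if (!is.null(tr)) {
      path <- fp(paste0("consensus_", nm, ".nwk"))
      ape::write.tree(tr, path)
      files <- c(files, path)
    }
  }
  manifest <- list(
    package = "ssrflank",
    version = as.character(utils::packageVersion("ssrflank")),
    seed = bundle$config$seed, stage_seeds = bundle$seeds,
    settings = bundle$config[c("repeat_weight", "amova_permutations",
                               "mantel_permutations", "mcmc_steps",
                               "mcmc_burnin", "alpha")],
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Per-locus polymorphism summary table (wide layout)
#'
#' One row per locus: amplicon-size and whole-sequence diversity, per-block
#' repeat diversity (up to three blocks; absent blocks are dashes), flanking
#' length, SNP and indel counts, SNP density per 100 bp, and flanking
#' haplotype diversity.
#'
#' @param bundle A report bundle from [run_pipeline()], or a data frame as
#'   returned by [summarize_locus()].
#' @return A data frame, one row per locus.
#' @export
make_table3 <- function(bundle) {
  div <- if (is.data.frame(bundle)) bundle else bundle$diversity
  loci <- unique(div$locus)
  rows <- lapply(loci, function(lc) {
    d <- div[div$locus == lc, ]
    g <- function(comp, col) {
      v <- d[d$component == comp, col]
      if (!length(v) || is.na(v)) "-" else
        if (is.numeric(v)) formatC(v, format = "fg", digits = 4) else v
    }
    data.frame(
      locus = lc,
      size_He = g("size", "He"), size_A = g("size", "A"),
      full_He = g("full", "He"), full_h = g("full", "h"),
      ssr1_He = g("repeat1", "He"), ssr1_A = g("repeat1", "A"),
      ssr2_He = g("repeat2", "He"), ssr2_A = g("repeat2", "A"),
      ssr3_He = g("repeat3", "He"), ssr3_A = g("repeat3", "A"),
      fr_length_bp = g("fr", "fr_length_bp"),
      n_snps = g("fr", "n_snps"),
      snps_per_100bp = g("fr", "snp_density"),
      n_indels = g("fr", "n_indels"),
      fr_He = g("fr", "He"), fr_h = g("fr", "h"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
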