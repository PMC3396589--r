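#' Construct an annotated amplicon alignment
#'
#' The central data container: a gapped multiple alignment of sequenced SSR
#' allele copies at one locus, with repeat-block annotations on the consensus
#' (1-based inclusive column coordinates) and a population label per allele.
#'
#' @param locus Locus identifier.
#' @param seqs Named character vector of gapped sequences (over `A,C,G,T,-`),
#'   all of equal length; names are sample ids.
#' @param populations Character vector of population labels, named by sample
#'   id (or unnamed, parallel to `seqs`).
#' @param blocks Data frame with columns `block`, `motif`, `start`, `end`
#'   giving each repeat block's motif and consensus column span.
#' @return An object of class `amplicon_alignment`.
#' @export
amplicon_alignment <- function(locus, seqs, populations, blocks) {
  seqs <- toupper(seqs)
  if (is.null(names(seqs))) stop("sequences must be named by sample id")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != stats::median(lens)][1L]
    stop("ragged alignment: record '", bad, "' has ", nchar(seqs[bad]),
         " columns, expected ", stats::median(lens))
  }
  n_col <- unname(lens[1L])
  if (any(!grepl("^[ACGTN-]*$", seqs)))
    stop("sequences may contain only A, C, G, T, N and '-'")
  if (is.null(names(populations))) names(populations) <- names(seqs)
  populations <- populations[names(seqs)]
  if (anyNA(populations)) stop("every sample needs a population label")
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  if (nrow(blocks)) {
    if (any(blocks$start < 1L) || any(blocks$end > n_col))
      stop("block annotation span exceeds consensus length (", n_col, ")")
    if (any(blocks$end < blocks$start)) stop("block end before start")
    if (nrow(blocks) > 1L &&
        any(blocks$start[-1L] <= blocks$end[-nrow(blocks)]))
      stop("block spans must be disjoint")
    blocks$degenerate <- (blocks$end - blocks$start + 1L) %%
      nchar(blocks$motif) != 0L
  }
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  structure(list(locus = locus, ids = names(seqs), seqs = seqs, mat = mat,
                 populations = populations, n_col = n_col, blocks = blocks),
            class = "amplicon_alignment")
}

#' @export
print.amplicon_alignment <- function(x, ...) {
  cat("Amplicon alignment '", x$locus, "': ", length(x$ids), " alleles x ",
      x$n_col, " columns, ", nrow(x$blocks), " repeat block(s) [",
      paste0("(", x$blocks$motif, ")", collapse = " "), "], ",
      length(unique(x$populations)), " population(s)\n", sep = "")
  invisible(x)
}

#' Read an amplicon alignment from FASTA + annotation + population map
#'
#' @param fasta_path Gapped FASTA file.
#' @param annotation_path TSV with columns `locus`, `block`, `motif`, `start`,
#'   `end` (1-based inclusive consensus columns).
#' @param popmap_path TSV with columns `sample_id`, `population`.
#' @param locus Locus to extract from the annotation (default: first).
#' @param allow_unassigned If `TRUE`, samples missing from the popmap get
#'   population `"unassigned"` instead of an error.
#' @return An [amplicon_alignment()].
#' @export
read_amplicon_alignment <- function(fasta_path, annotation_path, popmap_path,
                                    locus = NULL, allow_unassigned = FALSE) {
  for (p in c(fasta_path, annotation_path, popmap_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  seqs <- as.character(Biostrings::readBStringSet(fasta_path))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (is.null(locus)) locus <- ann$locus[1L]
  blocks <- ann[ann$locus == locus, c("block", "motif", "start", "end")]
  if (!nrow(blocks)) stop("no annotation rows for locus '", locus, "'")
  pm <- utils::read.delim(popmap_path, stringsAsFactors = FALSE)
  pops <- stats::setNames(pm$population, pm$sample_id)[names(seqs)]
  if (anyNA(pops)) {
    missing <- names(seqs)[is.na(pops)]
    if (!allow_unassigned)
      stop("samples missing from popmap: ", paste(missing, collapse = ", "))
    pops[is.na(pops)] <- "unassigned"
  }
  names(pops) <- names(seqs)
  amplicon_alignment(locus, seqs, pops, blocks)
}

#' Write an amplicon alignment (FASTA + annotation + popmap)
#'
#' @param aln An [amplicon_alignment()].
#' @param fasta_path,annotation_path,popmap_path Output paths (any may be
#'   `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_amplicon_alignment <- function(aln, fasta_path, annotation_path = NULL,
                                     popmap_path = NULL) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), fasta_path)
  if (!is.null(annotation_path)) {
    ann <- cbind(locus = aln$locus,
                 aln$blocks[, c("block", "motif", "start", "end")])
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(popmap_path))
    utils::write.table(data.frame(sample_id = aln$ids,
                                  population = unname(aln$populations)),
                       popmap_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(fasta_path, annotation_path, popmap_path))
}

# columns covered by repeat blocks
.block_cols <- function(aln) {
  if (!nrow(aln$blocks)) return(integer(0))
  unlist(Map(seq.int, aln$blocks$start, aln$blocks$end))
}

#' Call polymorphic sites (SNPs and indel runs)
#'
#' SNP sites are variable columns (at least two distinct bases among non-gap
#' alleles); alleles gapped at a SNP column carry a missing state. Each
#' maximal flanking gap run with an identical presence pattern across alleles
#' is coded as ONE binary mutational event regardless of its length; runs with
#' partially overlapping spans are split at span boundaries so every indel
#' site stays binary. Gaps inside repeat blocks are repeat-length padding and
#' never become indel sites; variable in-block columns are flagged
#' `in_repeat` and excluded from flanking-region site lists.
#'
#' @param aln An [amplicon_alignment()].
#' @return An object of class `ssr_sites`: list with `table` (one row per
#'   site: `site`, `kind`, `start`, `end`, `in_repeat`, `n_states`) and
#'   `states` (alleles x sites character matrix, `NA` = missing).
#' @export
call_sites <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat)
  bcols <- .block_cols(aln)
  fr_cols <- setdiff(seq_len(aln$n_col), bcols)

  site_rows <- list()
  state_cols <- list()
  add_site <- function(kind, start, end, in_repeat, states) {
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      site = sprintf("%s_%d", kind, start), kind = kind, start = start,
      end = end, in_repeat = in_repeat,
      n_states = length(unique(states[!is.na(states)])),
      stringsAsFactors = FALSE)
    state_cols[[length(state_cols) + 1L]] <<- states
  }

  # indel runs: group contiguous flanking gap columns by gap pattern
  gap <- mat == "-"
  cand <- fr_cols[colSums(gap[, fr_cols, drop = FALSE]) > 0L]
  if (length(cand)) {
    pat <- apply(gap[, cand, drop = FALSE], 2L, paste, collapse = "")
    brk <- c(TRUE, diff(cand) != 1L | pat[-1L] != pat[-length(pat)])
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      cols <- cand[grp == g]
      absent <- gap[, cols[1L]]
      if (all(absent) || !any(absent)) next       # monomorphic, not a site
      states <- ifelse(absent, "del", "ins")
      add_site("indel", cols[1L], cols[length(cols)], FALSE, states)
    }
  }
  indel_cols <- unlist(lapply(site_rows, function(r)
    if (r$kind == "indel") r$start:r$end else integer(0)))

  # SNP sites: variable columns among non-gap alleles
  for (col in seq_len(aln$n_col)) {
    x <- mat[, col]
    x[x == "-" | x == "N"] <- NA
    obs <- unique(x[!is.na(x)])
    if (length(obs) < 2L) next
    add_site("snp", col, col, col %in% bcols, x)
  }

  tab <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(site = character(0), kind = character(0), start = integer(0),
               end = integer(0), in_repeat = logical(0),
               n_states = integer(0))
  ord <- order(tab$start, tab$end)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  states <- if (length(state_cols))
    do.call(cbind, state_cols)[, ord, drop = FALSE] else
    matrix(character(0), n, 0)
  rownames(states) <- rownames(mat)
  colnames(states) <- tab$site
  structure(list(table = tab, states = states, ids = rownames(mat),
                 locus = aln$locus), class = "ssr_sites")
}

#' @export
print.ssr_sites <- function(x, ...) {
  cat("Polymorphic sites at '", x$locus, "': ",
      sum(x$table$kind == "snp" & !x$table$in_repeat), " FR SNPs, ",
      sum(x$table$kind == "indel"), " FR indel runs, ",
      sum(x$table$in_repeat), " in-repeat SNPs\n", sep = "")
  invisible(x)
}

#' Decompose each allele into the four components of variation
#'
#' Per allele: amplicon size (ungapped length), repeat count per block
#' (non-gap in-block length divided by motif length), flanking-region
#' haplotype (states over flanking sites), and whole-sequence haplotype
#' (ungapped sequence). Alleles whose repeat block carries an off-motif base
#' are flagged `imperfect` (excluded from repeat-count analyses downstream);
#' blocks whose non-gap length is not a multiple of the motif length flag the
#' allele `degenerate`.
#'
#' For perfect alleles the identity
#' `amplicon_size = ungapped flanking length + sum(repeat_count * motif
#' length)` holds exactly.
#'
#' @param aln An [amplicon_alignment()].
#' @param sites Sites from [call_sites()] (computed if missing).
#' @return An object of class `allele_decomposition`: list with `alleles`
#'   (one row per allele), `repeats` (matrix), `fr_states`, `sites`, and
#'   locus metadata.
#' @export
decompose_alleles <- function(aln, sites = call_sites(aln)) {
  mat <- aln$mat
  n <- nrow(mat)
  B <- nrow(aln$blocks)
  motif_len <- nchar(aln$blocks$motif)
  reps <- matrix(NA_integer_, n, B,
                 dimnames = list(rownames(mat),
                                 if (B) paste0("block", seq_len(B))))
  imperfect <- logical(n)
  degenerate <- logical(n)
  for (b in seq_len(B)) {
    cols <- aln$blocks$start[b]:aln$blocks$end[b]
    for (i in seq_len(n)) {
      chars <- mat[i, cols]
      chars <- chars[chars != "-"]
      len <- length(chars)
      if (len %% motif_len[b] != 0L) {
        degenerate[i] <- TRUE
        next
      }
      cnt <- len %/% motif_len[b]
      reps[i, b] <- cnt
      if (cnt > 0L &&
          paste(chars, collapse = "") != strrep(aln$blocks$motif[b], cnt))
        imperfect[i] <- TRUE
    }
  }
  if (any(degenerate))
    warning("allele(s) with in-block length not a multiple of the motif: ",
            paste(rownames(mat)[degenerate], collapse = ", "),
            " (flagged degenerate, excluded from repeat analyses)")

  ungapped <- apply(mat, 1L, function(r) sum(r != "-"))
  seq_key <- apply(mat, 1L, function(r) paste(r[r != "-"], collapse = ""))
  fr_idx <- which(!sites$table$in_repeat)
  fr_states <- sites$states[, fr_idx, drop = FALSE]
  fr_key <- apply(fr_states, 1L, function(r)
    paste(ifelse(is.na(r), ".", r), collapse = "|"))
  total_repeat_bp <- if (B) as.integer(reps %*% motif_len) else
    rep(0L, n)

  alleles <- data.frame(
    sample_id = rownames(mat),
    population = unname(aln$populations[rownames(mat)]),
    amplicon_size = unname(ungapped),
    total_repeat_bp = total_repeat_bp,
    imperfect = imperfect,
    degenerate = degenerate,
    fr_haplotype = unname(fr_key),
    seq_haplotype = unname(seq_key),
    stringsAsFactors = FALSE)
  structure(list(alleles = alleles, repeats = reps, fr_states = fr_states,
                 sites = sites, locus = aln$locus,
                 motifs = aln$blocks$motif, motif_len = motif_len,
                 fr_length = aln$n_col - length(.block_cols(aln))),
            class = "allele_decomposition")
}

#' @export
print.allele_decomposition <- function(x, ...) {
  cat("Allele decomposition at '", x$locus, "': ", nrow(x$alleles),
      " alleles, ", ncol(x$repeats), " repeat block(s), ",
      ncol(x$fr_states), " FR site(s); ", sum(x$alleles$imperfect),
      " imperfect, ", sum(x$alleles$degenerate), " degenerate\n", sep = "")
  invisible(x)
}

# allele subset of a decomposition (used for pairwise-population analyses)
.subset_decomposition <- function(dec, keep) {
  dec$alleles <- dec$alleles[keep, , drop = FALSE]
  dec$repeats <- dec$repeats[keep, , drop = FALSE]
  dec$fr_states <- dec$fr_states[keep, , drop = FALSE]
  dec
}

#' Detect and classify amplicon size homoplasy
#'
#' Groups alleles by exact amplicon size; an allele is homoplasious if its
#' whole-amplicon sequence differs from at least one other allele of the same
#' size. Each differing equal-size pair is classified, with precedence
#' i > ii > iii:
#' * **i** — a flanking indel compensates a difference in repeat length
#'   (total repeat bp differs between the two alleles);
#' * **ii** — compound repeats redistribute the same total repeat length over
#'   different blocks (same total repeat bp, different per-block counts);
#' * **iii** — same size and repeat counts, but sequences differ by SNPs
#'   (flanking or in-repeat).
#'
#' @param dec An [decompose_alleles()] result.
#' @return An object of class `homoplasy_report`: summary counts, the
#'   percentage of size-sharing allele copies that are homoplasious (rounded
#'   to the nearest integer; `NA` if no two alleles share a size), per-group
#'   table and classified pair table.
#' @export
detect_homoplasy <- function(dec) {
  al <- dec$alleles
  if (nrow(al) < 2L) stop("need at least 2 alleles")
  groups <- split(seq_len(nrow(al)), al$amplicon_size)
  pair_rows <- list()
  homoplasious <- logical(nrow(al))
  for (g in groups) {
    if (length(g) < 2L) next
    for (a in seq_along(g)[-length(g)]) for (b in (a + 1L):length(g)) {
      i <- g[a]; j <- g[b]
      if (al$seq_haplotype[i] == al$seq_haplotype[j]) next
      homoplasious[c(i, j)] <- TRUE
      same_bp <- isTRUE(al$total_repeat_bp[i] == al$total_repeat_bp[j])
      cls <- if (!same_bp) "i"
      else if (!isTRUE(all(dec$repeats[i, ] == dec$repeats[j, ]))) "ii"
      else "iii"
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        allele_a = al$sample_id[i], allele_b = al$sample_id[j],
        amplicon_size = al$amplicon_size[i], class = cls,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(allele_a = character(0), allele_b = character(0),
               amplicon_size = integer(0), class = character(0))
  sharing <- vapply(groups, length, integer(1))
  n_sharing <- sum(sharing[sharing >= 2L])
  n_homo <- sum(homoplasious)
  group_tab <- data.frame(
    amplicon_size = as.integer(names(groups)),
    n_alleles = unname(sharing),
    homoplasy = vapply(groups, function(g)
      length(unique(al$seq_haplotype[g])) > 1L, logical(1)),
    row.names = NULL)
  structure(list(groups = group_tab, pairs = pairs,
                 n_size_sharing = n_sharing, n_homoplasious = n_homo,
                 percent = if (n_sharing) round(100 * n_homo / n_sharing)
                           else NA_real_,
                 locus = dec$locus),
            class = "homoplasy_report")
}

#' @export
print.homoplasy_report <- function(x, ...) {
  cat("Size homoplasy at '", x$locus, "': ", x$n_homoplasious, " of ",
      x$n_size_sharing, " size-sharing allele copies (",
      if (is.na(x$percent)) "not applicable" else paste0(x$percent, "%"),
      ")\n", sep = "")
  if (nrow(x$pairs))
    print(table(class = x$pairs$class))
  invisible(x)
}
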