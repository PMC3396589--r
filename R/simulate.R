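#' Simulation configuration for SSR amplicon evolution
#'
#' Bundles every parameter of the coalescent simulator: demography, repeat-block
#' layout, and mutation rates for the three mutational processes acting on an
#' SSR amplicon (repeat-count mutation in the SSR blocks, substitutions and
#' indels in the flanking regions).
#'
#' Defaults emulate a sequenced-amplicon study design: four populations of 25
#' haploid allele copies, one dinucleotide repeat block, a ~150 bp flanking
#' region, and a repeat mutation rate several orders of magnitude above the
#' per-site substitution rate.
#'
#' @param n_pops Number of populations.
#' @param samples_per_pop Haploid allele copies sampled per population
#'   (scalar, recycled, or a vector of length `n_pops`).
#' @param effective_size Haploid effective population size `N`; coalescence
#'   rate per lineage pair is `1/N` per generation.
#' @param demography Either `list(kind = "island", migration_rate = m)` for a
#'   symmetric island model (per-lineage backward migration rate `m` per
#'   generation) or `list(kind = "split_tree", tree = <newick>)` where the
#'   newick string is an ultrametric population tree with branch lengths in
#'   generations.
#' @param n_blocks Number of repeat blocks in the amplicon.
#' @param motifs Repeat unit per block (character vector of length `n_blocks`).
#' @param init_repeats Ancestral repeat count per block (length `n_blocks` or
#'   scalar).
#' @param mu_ssr Repeat mutations per lineage per generation per block.
#' @param ssr_model `"SMM"` (single-step) or `"GSM"` (geometric step sizes).
#' @param p_geom Success probability of the geometric step-size distribution
#'   under GSM (mean step `1/p_geom`).
#' @param fr_length Total flanking-region length in bp (split into
#'   `n_blocks + 1` segments around the repeat blocks).
#' @param mu_snp Substitutions per flanking site per generation.
#' @param mu_indel Indel events per amplicon per generation.
#' @param indel_mean_bp Mean indel run length (geometric distribution on
#'   `1, 2, ...`).
#' @param locus Locus identifier used in rendered outputs.
#' @param seed Optional RNG seed for reproducible simulation.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pops = 4L,
                       samples_per_pop = 25L,
                       effective_size = 1000,
                       demography = list(kind = "island", migration_rate = 1e-3),
                       n_blocks = 1L,
                       motifs = "GA",
                       init_repeats = 12L,
                       mu_ssr = 2.5e-3,
                       ssr_model = c("SMM", "GSM"),
                       p_geom = 0.5,
                       fr_length = 150L,
                       mu_snp = 6e-6,
                       mu_indel = 2e-4,
                       indel_mean_bp = 8,
                       locus = "locus1",
                       seed = NULL) {
  ssr_model <- match.arg(ssr_model)
  n_pops <- as.integer(n_pops)
  samples_per_pop <- as.integer(rep_len(samples_per_pop, n_pops))
  n_blocks <- as.integer(n_blocks)
  motifs <- rep_len(as.character(motifs), n_blocks)
  init_repeats <- as.integer(rep_len(init_repeats, n_blocks))
  fr_length <- as.integer(fr_length)

  stopifnot(n_pops >= 1L, effective_size > 0, n_blocks >= 1L)
  if (any(samples_per_pop < 2L) && sum(samples_per_pop) > 1L)
    stop("samples_per_pop must all be >= 2 (or a single copy in total)")
  if (any(init_repeats < 2L)) stop("init_repeats must be >= 2 per block")
  if (fr_length < 1L) stop("fr_length must be >= 1")
  if (any(c(mu_ssr, mu_snp, mu_indel) < 0)) stop("mutation rates must be >= 0")
  if (!nzchar(demography$kind) || !demography$kind %in% c("island", "split_tree"))
    stop("demography$kind must be 'island' or 'split_tree'")
  if (demography$kind == "island") {
    if (n_pops > 1L && (is.null(demography$migration_rate) ||
                        demography$migration_rate <= 0))
      stop("island demography with > 1 population needs migration_rate > 0 ",
           "(lineages in distinct demes could never coalesce)")
  } else {
    if (is.null(demography$tree)) stop("split_tree demography needs a newick tree")
  }
  if (!all(grepl("^[ACGT]+$", motifs))) stop("motifs must be ACGT strings")
  if (p_geom <= 0 || p_geom > 1) stop("p_geom must be in (0, 1]")
  if (indel_mean_bp < 1) stop("indel_mean_bp must be >= 1")

  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 effective_size = effective_size, demography = demography,
                 n_blocks = n_blocks, motifs = motifs,
                 init_repeats = init_repeats, mu_ssr = mu_ssr,
                 ssr_model = ssr_model, p_geom = p_geom,
                 fr_length = fr_length, mu_snp = mu_snp,
                 mu_indel = mu_indel, indel_mean_bp = indel_mean_bp,
                 locus = locus, seed = seed),
            class = "sim_config")
}

# Build an ape "phylo" from a chronological merge list.
# merges: list of c(child1, child2) node ids; times: merge times (increasing);
# node_time: times of all nodes created so far (tips at 0).
.build_phylo <- function(n, merges, merge_times, node_time, tip_labels) {
  if (n == 1L) {
    phy <- structure(list(edge = matrix(integer(0), 0, 2),
                          edge.length = numeric(0),
                          tip.label = tip_labels, Nnode = 0L),
                     class = "phylo")
    return(phy)
  }
  n_int <- length(merges)                      # == n - 1
  # chronological internal id n + j  ->  phylo id 2n - j (root = n + 1)
  remap <- function(v) ifelse(v <= n, v, 2L * n - (v - n))
  edge <- matrix(0L, 2L * n_int, 2L)
  elen <- numeric(2L * n_int)
  for (j in seq_len(n_int)) {
    ch <- merges[[j]]
    pid <- remap(n + j)
    edge[2L * j - 1L, ] <- c(pid, remap(ch[1L]))
    edge[2L * j, ]      <- c(pid, remap(ch[2L]))
    elen[2L * j - 1L] <- merge_times[j] - node_time[ch[1L]]
    elen[2L * j]      <- merge_times[j] - node_time[ch[2L]]
  }
  # edge rows stay in chronological merge order: most recent merges first,
  # the two root edges last; traversal helpers below rely on this
  structure(list(edge = edge, edge.length = elen,
                 tip.label = tip_labels, Nnode = n_int),
            class = "phylo")
}

# Structured coalescent under the symmetric island model.
# Returns merges/times for .build_phylo.
.coalesce_island <- function(deme, N, m) {
  n <- length(deme)
  n_demes <- max(deme)
  act_node <- seq_len(n)
  act_deme <- deme
  node_time <- rep(0, n)
  merges <- vector("list", n - 1L)
  merge_times <- numeric(n - 1L)
  t <- 0
  j <- 0L
  while (length(act_node) > 1L) {
    k <- tabulate(act_deme, nbins = n_demes)
    coal_rate <- k * (k - 1) / 2 / N
    mig_rate <- if (n_demes > 1L) length(act_node) * m else 0
    total <- sum(coal_rate) + mig_rate
    t <- t + stats::rexp(1L, total)
    if (stats::runif(1L) < sum(coal_rate) / total) {
      d <- sample.int(n_demes, 1L, prob = coal_rate)
      idx <- which(act_deme == d)
      pair <- idx[sample.int(length(idx), 2L)]
      j <- j + 1L
      merges[[j]] <- act_node[pair]
      merge_times[j] <- t
      new_id <- n + j
      node_time[new_id] <- t
      act_node <- c(act_node[-pair], new_id)
      act_deme <- c(act_deme[-pair], d)
    } else {
      i <- sample.int(length(act_node), 1L)
      others <- setdiff(seq_len(n_demes), act_deme[i])
      act_deme[i] <- others[sample.int(length(others), 1L)]
    }
  }
  list(merges = merges, merge_times = merge_times, node_time = node_time)
}

# Structured coalescent under a fixed population split tree (no migration).
.coalesce_split <- function(deme, N, poptree, pop_names) {
  n <- length(deme)
  nt <- ape::Ntip(poptree)
  if (!setequal(poptree$tip.label, pop_names))
    stop("split tree tips must match population names")
  bt <- ape::branching.times(poptree)          # named by internal node id
  ev_nodes <- as.integer(names(sort(bt)))      # merges, oldest last
  ev_times <- as.numeric(sort(bt))
  tipsets <- lapply(seq_len(nt + poptree$Nnode), function(v) {
    if (v <= nt) poptree$tip.label[v]
    else ape::extract.clade(poptree, v)$tip.label
  })
  act_node <- seq_len(n)
  act_clust <- deme                             # clusters start as demes
  node_time <- rep(0, n)
  merges <- vector("list", n - 1L)
  merge_times <- numeric(n - 1L)
  t <- 0
  j <- 0L
  advance <- function(t_end) {
    # coalesce within clusters until t_end (Inf for final epoch)
    repeat {
      ks <- table(act_clust)
      rates <- as.numeric(ks) * (as.numeric(ks) - 1) / 2 / N
      total <- sum(rates)
      if (total == 0) { t <<- t_end; return(invisible()) }
      dt <- stats::rexp(1L, total)
      if (t + dt > t_end) { t <<- t_end; return(invisible()) }
      t <<- t + dt
      ci <- as.integer(names(ks))[sample.int(length(ks), 1L, prob = rates)]
      idx <- which(act_clust == ci)
      pair <- idx[sample.int(length(idx), 2L)]
      j <<- j + 1L
      merges[[j]] <<- act_node[pair]
      merge_times[j] <<- t
      new_id <- n + j
      node_time[new_id] <<- t
      act_node <<- c(act_node[-pair], new_id)
      act_clust <<- c(act_clust[-pair], ci)
      if (length(act_node) == 1L) return(invisible())
    }
  }
  for (e in seq_along(ev_nodes)) {
    advance(ev_times[e])
    if (length(act_node) == 1L) break
    # merge the two child clusters of this split node
    kids <- poptree$edge[poptree$edge[, 1] == ev_nodes[e], 2]
    pops_a <- match(tipsets[[kids[1]]], pop_names)
    pops_b <- match(tipsets[[kids[2]]], pop_names)
    target <- min(c(pops_a, pops_b))
    # relabel any lineage whose cluster is one of the merged pop-derived ids
    merged_ids <- unique(c(pops_a, pops_b))
    act_clust[act_clust %in% merged_ids] <- target
  }
  if (length(act_node) > 1L) advance(Inf)
  list(merges = merges, merge_times = merge_times, node_time = node_time)
}

#' Simulate a coalescent genealogy of sampled allele copies
#'
#' Generates a Kingman-coalescent genealogy (haploid scaling: expected pairwise
#' coalescence time `N` generations) under either a symmetric island model or
#' a fixed population split tree.
#'
#' @param config A [sim_config()].
#' @return An `ape::phylo` tree with branch lengths in generations and an extra
#'   element `population`: a character vector of population labels named by
#'   tip label.
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pops <- paste0("P", seq_len(config$n_pops))
  deme <- rep(seq_len(config$n_pops), config$samples_per_pop)
  n <- length(deme)
  tip_labels <- unlist(lapply(seq_len(config$n_pops), function(p)
    paste0(pops[p], "_", seq_len(config$samples_per_pop[p]))))
  if (n == 1L) {
    phy <- .build_phylo(1L, list(), numeric(0), 0, tip_labels)
  } else {
    res <- if (config$demography$kind == "island") {
      .coalesce_island(deme, config$effective_size,
                       config$demography$migration_rate)
    } else {
      poptree <- ape::read.tree(text = config$demography$tree)
      .coalesce_split(deme, config$effective_size, poptree, pops)
    }
    phy <- .build_phylo(n, res$merges, res$merge_times, res$node_time,
                        tip_labels)
  }
  phy$population <- stats::setNames(pops[deme], tip_labels)
  phy
}

# tips (tip indices) below the child node of each edge; relies on the
# chronological edge order of .build_phylo (a child's own edges precede the
# edge pointing to it)
.edge_tip_sets <- function(phy) {
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  below <- vector("list", m)
  for (i in seq_len(n)) below[[i]] <- i
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(phy$edge)), function(e) sort(below[[phy$edge[e, 2]]]))
}

# edges ordered parent-before-child (preorder): reverse chronological order
.preorder_edges <- function(phy) rev(seq_len(nrow(phy$edge)))

#' Evolve repeat counts along a genealogy
#'
#' Drops repeat-count mutations on each branch (Poisson with mean
#' `mu_ssr * branch length` per block) and applies them under the stepwise
#' mutation model (steps of +/-1 repeat) or the generalized stepwise model
#' (geometric step magnitudes). Counts reflect at the single-repeat boundary:
#' a step below 1 bounces back (`0 -> 2`), since a locus with no repeats is
#' unobservable as an SSR.
#'
#' @param gen Genealogy from [simulate_genealogy()].
#' @param config The [sim_config()] used to generate it.
#' @return A list with `repeats` (tips x blocks integer matrix of repeat
#'   counts, rownames = tip labels) and `n_mutations` (edges x blocks matrix of
#'   mutation counts per branch).
#' @export
mutate_ssr <- function(gen, config) {
  n <- length(gen$tip.label)
  B <- config$n_blocks
  nE <- nrow(gen$edge)
  state <- matrix(NA_integer_, n + max(gen$Nnode, 1L), B)
  root <- n + 1L
  if (nE == 0L) {
    reps <- matrix(config$init_repeats, n, B, byrow = TRUE,
                   dimnames = list(gen$tip.label, NULL))
    return(list(repeats = reps, n_mutations = matrix(0L, 0, B)))
  }
  state[root, ] <- config$init_repeats
  nmut <- matrix(0L, nE, B)
  for (e in .preorder_edges(gen)) {
    p <- gen$edge[e, 1]; ch <- gen$edge[e, 2]
    len <- gen$edge.length[e]
    for (b in seq_len(B)) {
      k <- stats::rpois(1L, config$mu_ssr * len)
      nmut[e, b] <- k
      x <- state[p, b]
      if (k > 0L) {
        for (s in seq_len(k)) {
          step <- if (config$ssr_model == "SMM") 1L
                  else stats::rgeom(1L, config$p_geom) + 1L
          if (stats::runif(1L) < 0.5) step <- -step
          x <- x + step
          if (x < 1L) x <- 2L - x           # reflect at 1
        }
      }
      state[ch, b] <- x
    }
  }
  reps <- state[seq_len(n), , drop = FALSE]
  rownames(reps) <- gen$tip.label
  list(repeats = reps, n_mutations = nmut)
}

# split fr_length into n_blocks + 1 segments (lengths, as even as possible)
.fr_segments <- function(config) {
  k <- config$n_blocks + 1L
  base <- config$fr_length %/% k
  lens <- rep(base, k)
  extra <- config$fr_length - base * k
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  if (any(lens < 1L)) stop("fr_length too short for the number of blocks")
  ends <- cumsum(lens)
  data.frame(segment = seq_len(k), start = ends - lens + 1L, end = ends)
}

#' Evolve flanking-region SNPs and indels along a genealogy
#'
#' Substitutions follow the infinite-sites model: the number of mutations is
#' Poisson with mean `mu_snp * fr_length * total tree length`, each hits a new
#' uniformly chosen flanking site and is assigned to a branch with probability
#' proportional to branch length. Indel events likewise each create one new
#' non-overlapping gap run (geometric length, entirely within one flanking
#' segment) and are treated as deletions relative to the rendered consensus.
#'
#' @inheritParams mutate_ssr
#' @return A list with the ancestral flanking sequence (`consensus_fr`), SNP
#'   and indel event tables (`snps`, `indels`, with the branch each sits on),
#'   and per-tip rendered states (`snp_states`, `indel_absent`).
#' @export
mutate_fr <- function(gen, config) {
  n <- length(gen$tip.label)
  nE <- nrow(gen$edge)
  L <- config$fr_length
  total_len <- if (nE) sum(gen$edge.length) else 0
  consensus <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  segs <- .fr_segments(config)

  n_indel <- if (config$mu_indel > 0 && total_len > 0)
    stats::rpois(1L, config$mu_indel * total_len) else 0L
  occupied <- logical(L)   # flanking positions covered by (or adjacent to) runs
  indels <- data.frame(start = integer(0), length = integer(0),
                       edge = integer(0))
  if (n_indel > 0L) {
    for (i in seq_len(n_indel)) {
      len_i <- stats::rgeom(1L, 1 / config$indel_mean_bp) + 1L
      # all starts whose run fits one segment and whose guard window (one
      # spare column on each side, keeping runs separated) is free
      feasible <- integer(0)
      for (s in seq_len(nrow(segs))) {
        if (segs$end[s] - segs$start[s] + 1L < len_i) next
        for (st in segs$start[s]:(segs$end[s] - len_i + 1L)) {
          guard <- max(1L, st - 1L):min(L, st + len_i)
          if (!any(occupied[guard])) feasible <- c(feasible, st)
        }
      }
      if (!length(feasible))
        stop("could not place an indel run of ", len_i, " bp without ",
             "overlap; reduce mu_indel or indel_mean_bp")
      st <- feasible[sample.int(length(feasible), 1L)]
      occupied[st:(st + len_i - 1L)] <- TRUE
      indels <- rbind(indels, data.frame(start = st, length = len_i,
                                         edge = NA_integer_))
    }
    indels$edge <- sample.int(nE, nrow(indels), replace = TRUE,
                              prob = gen$edge.length)
  }

  run_cols <- integer(0)
  if (nrow(indels)) run_cols <- unlist(Map(function(s, l) s:(s + l - 1L),
                                           indels$start, indels$length))
  free <- setdiff(seq_len(L), run_cols)
  n_snp <- if (config$mu_snp > 0 && total_len > 0)
    stats::rpois(1L, config$mu_snp * L * total_len) else 0L
  if (n_snp > length(free))
    stop("more SNP mutations (", n_snp, ") than available flanking sites (",
         length(free), "); shorten the tree or lower mu_snp")
  snps <- data.frame(col = integer(0), edge = integer(0),
                     anc = character(0), der = character(0))
  if (n_snp > 0L) {
    cols <- sort(free[sample.int(length(free), n_snp)])
    edges <- sample.int(nE, n_snp, replace = TRUE, prob = gen$edge.length)
    anc <- consensus[cols]
    der <- vapply(anc, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    snps <- data.frame(col = cols, edge = edges, anc = anc, der = der,
                       stringsAsFactors = FALSE, row.names = NULL)
  }

  tipsets <- if (nE) .edge_tip_sets(gen) else list()
  snp_states <- matrix(rep(consensus[snps$col], each = n), n, nrow(snps),
                       dimnames = list(gen$tip.label, NULL))
  if (nrow(snps)) for (s in seq_len(nrow(snps)))
    snp_states[tipsets[[snps$edge[s]]], s] <- snps$der[s]
  indel_absent <- matrix(FALSE, n, nrow(indels),
                         dimnames = list(gen$tip.label, NULL))
  if (nrow(indels)) for (i in seq_len(nrow(indels)))
    indel_absent[tipsets[[indels$edge[i]]], i] <- TRUE

  list(consensus_fr = consensus, snps = snps, indels = indels,
       snp_states = snp_states, indel_absent = indel_absent)
}

#' Render a simulated truth record as a gapped amplicon alignment
#'
#' Lays the amplicon out as alternating flanking segments and repeat blocks.
#' Each block is rendered as the motif repeated the tip's repeat count and
#' right-padded with gap characters to the widest allele; flanking indel
#' carriers get gap runs. The decomposition of the rendered alignment recovers
#' the true repeat counts and flanking site counts exactly.
#'
#' @param truth A truth record as assembled by [simulate_locus()] (genealogy,
#'   `repeats`, `fr`).
#' @param config The [sim_config()] used.
#' @return An [amplicon_alignment()] object.
#' @export
render_alignment <- function(truth, config) {
  gen <- truth$genealogy
  n <- length(gen$tip.label)
  B <- config$n_blocks
  segs <- .fr_segments(config)
  motif_len <- nchar(config$motifs)
  block_width <- vapply(seq_len(B), function(b)
    max(truth$repeats[, b]) * as.integer(motif_len[b]), integer(1))

  # alignment column index of each flanking position
  n_col <- config$fr_length + sum(block_width)
  fr_col <- integer(config$fr_length)
  blocks <- data.frame(block = seq_len(B), motif = config$motifs,
                       start = integer(B), end = integer(B),
                       stringsAsFactors = FALSE)
  cursor <- 0L
  for (s in seq_len(nrow(segs))) {
    idx <- segs$start[s]:segs$end[s]
    fr_col[idx] <- cursor + seq_along(idx)
    cursor <- cursor + length(idx)
    if (s <= B) {
      blocks$start[s] <- cursor + 1L
      blocks$end[s] <- cursor + block_width[s]
      cursor <- cursor + as.integer(block_width[s])
    }
  }

  mat <- matrix("-", n, n_col, dimnames = list(gen$tip.label, NULL))
  mat[, fr_col] <- rep(truth$fr$consensus_fr, each = n)
  snps <- truth$fr$snps
  if (nrow(snps)) for (s in seq_len(nrow(snps)))
    mat[, fr_col[snps$col[s]]] <- truth$fr$snp_states[, s]
  ind <- truth$fr$indels
  if (nrow(ind)) for (i in seq_len(nrow(ind))) {
    span <- fr_col[ind$start[i]:(ind$start[i] + ind$length[i] - 1L)]
    mat[truth$fr$indel_absent[, i], span] <- "-"
  }
  for (b in seq_len(B)) {
    cols <- blocks$start[b]:blocks$end[b]
    for (i in seq_len(n)) {
      rep_str <- strsplit(strrep(config$motifs[b], truth$repeats[i, b]),
                          "")[[1]]
      row <- rep("-", length(cols))
      row[seq_along(rep_str)] <- rep_str
      mat[i, cols] <- row
    }
  }
  amplicon_alignment(locus = config$locus,
                     seqs = apply(mat, 1L, paste, collapse = ""),
                     populations = gen$population,
                     blocks = blocks)
}

#' Simulate one SSR locus end to end
#'
#' Runs [simulate_genealogy()], [mutate_ssr()], [mutate_fr()] and
#' [render_alignment()] and returns the rendered alignment together with the
#' complete truth record.
#'
#' @param config A [sim_config()].
#' @return A list of class `ssr_simulation` with elements `alignment`,
#'   `truth` (genealogy, repeat counts, flanking events, config) and `popmap`
#'   (data frame `sample_id`, `population`).
#' @export
simulate_locus <- function(config) {
  gen <- simulate_genealogy(config)
  ssr <- mutate_ssr(gen, config)
  fr <- mutate_fr(gen, config)
  truth <- list(genealogy = gen, repeats = ssr$repeats,
                ssr_mutations = ssr$n_mutations, fr = fr, config = config)
  aln <- render_alignment(truth, config)
  structure(list(alignment = aln, truth = truth,
                 popmap = data.frame(sample_id = gen$tip.label,
                                     population = unname(gen$population),
                                     stringsAsFactors = FALSE)),
            class = "ssr_simulation")
}

#' Simulate a multi-locus data set
#'
#' Loci are unlinked: each gets an independent genealogy. A single seed drives
#' the whole data set.
#'
#' @param configs A list of [sim_config()] objects (one per locus) or a single
#'   config to be reused with locus names `locus1..locusK`.
#' @param n_loci Number of loci when a single config is given.
#' @param seed Optional seed for the whole data set (overrides per-config
#'   seeds).
#' @return A list of `ssr_simulation` objects, named by locus.
#' @export
simulate_dataset <- function(configs, n_loci = NULL, seed = NULL) {
  if (inherits(configs, "sim_config")) {
    stopifnot(!is.null(n_loci))
    configs <- lapply(seq_len(n_loci), function(i) {
      cf <- configs; cf$locus <- paste0("locus", i); cf
    })
  }
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(configs, function(cf) {
    if (!is.null(seed)) cf$seed <- NULL   # share the seeded stream
    simulate_locus(cf)
  })
  names(sims) <- vapply(sims, function(s) s$alignment$locus, character(1))
  sims
}

#' Four-allele scenario where flanking and repeat signals conflict
#'
#' Constructs the textbook conflict between grouping alleles by flanking-region
#' haplotype and grouping them by repeat count: one flanking SNP (A/C) crossed
#' with two repeat counts (n, n+1), so that alleles with different repeat
#' counts share the same SNP state. Because SNPs mutate far slower than SSRs,
#' the most likely genealogy groups alleles by flanking haplotype, not repeat
#' count.
#'
#' @param n_repeats Smaller of the two repeat counts.
#' @param motif Repeat motif.
#' @param flank_bp Length of each flanking segment.
#' @return An [amplicon_alignment()] with four alleles `A_n`, `A_n1`, `C_n`,
#'   `C_n1` (SNP state x repeat class).
#' @export
conflict_scenario <- function(n_repeats = 10L, motif = "GA", flank_bp = 30L) {
  set.seed(20120699 %% .Machine$integer.max)  # fixed internal layout
  left <- sample(c("A", "C", "G", "T"), flank_bp, replace = TRUE)
  right <- sample(c("A", "C", "G", "T"), flank_bp, replace = TRUE)
  snp_pos <- flank_bp %/% 2L
  w <- (n_repeats + 1L) * nchar(motif)
  mk <- function(snp, reps) {
    l <- left; l[snp_pos] <- snp
    blk <- strsplit(strrep(motif, reps), "")[[1]]
    blk <- c(blk, rep("-", w - length(blk)))
    paste(c(l, blk, right), collapse = "")
  }
  seqs <- c(A_n  = mk("A", n_repeats),     A_n1 = mk("A", n_repeats + 1L),
            C_n  = mk("C", n_repeats),     C_n1 = mk("C", n_repeats + 1L))
  amplicon_alignment(
    locus = "conflict",
    seqs = seqs,
    populations = stats::setNames(rep("unassigned", 4L), names(seqs)),
    blocks = data.frame(block = 1L, motif = motif,
                        start = flank_bp + 1L, end = flank_bp + w,
                        stringsAsFactors = FALSE))
}
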