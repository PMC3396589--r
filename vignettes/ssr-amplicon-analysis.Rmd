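---
title: "Dissecting microsatellite amplicons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting microsatellite amplicons: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Microsatellite (SSR) markers are conventionally scored as PCR amplicon
lengths, on the assumption that length differences reflect differences in the
number of tandem repeats. But an amplicon is more than its repeat: the
flanking regions (FRs) on either side of the SSR can carry SNPs and
insertion/deletion runs of their own. Hidden flanking indels corrupt the
length-to-repeat-count mapping, and flanking SNPs make equally sized, equally
repeated alleles evolutionarily distinct — both are forms of *size
homoplasy*. Because repeats mutate orders of magnitude faster than flanking
sequence, the two compartments also record population history on different
timescales.

`ssrflank` takes per-locus multiple alignments of *sequenced* SSR amplicons
and separates the signal into four components of variation:

1. **amplicon size** (ungapped length in bp),
2. **repeat counts** per block (up to three blocks per amplicon),
3. **flanking-region haplotype** (SNPs plus indel runs),
4. **whole-amplicon sequence**.

Each component gets its own diversity summary, allele-level distance matrix,
and population-differentiation statistic, so the user can see directly when
the conventional size-based view and the sequence-based view disagree.

```{r}
library(ssrflank)
aln <- conflict_scenario()
aln
decompose_alleles(aln)
```

`conflict_scenario()` is the canonical four-allele illustration: one flanking
SNP (A/C) crossed with repeat counts (n, n+1). Grouping by flanking haplotype
contradicts grouping by repeat count; since SNPs mutate far more slowly than
repeats, the flanking grouping reflects the older part of the genealogy.

## Decomposition rules

* Coordinates are 1-based inclusive columns on the gapped consensus.
* **Indel runs are single events.** Each maximal flanking gap run with an
  identical presence/absence pattern across alleles is one binary site,
  whether it spans 1 bp or 66 bp. Runs with partially overlapping spans are
  split at span boundaries so every indel site stays binary — a convention we
  chose to keep the event coding unambiguous.
* **SNP sites** are columns with at least two distinct bases among non-gap
  alleles. Alleles gapped at a SNP column (because an indel run covers it)
  carry a *missing* state there; downstream pairwise analyses drop such
  alleles test-by-test rather than discarding the site.
* **Imperfect repeats.** An allele whose repeat block contains an off-motif
  base is flagged `imperfect`. It keeps its amplicon size (so size-component
  summaries stay comparable across the full sample) but leaves every
  repeat-count analysis, because no stepwise mutation model describes an
  interrupted repeat. In-block lengths that are not multiples of the motif
  flag the allele `degenerate` and exclude it likewise.
* For perfect alleles the identity
  `amplicon_size = ungapped FR length + sum(repeat_count x motif length)`
  holds exactly and is asserted on every simulated data set.
* **Size homoplasy** groups alleles by exact size (no binning — sequencing
  gives exact lengths). Within a group, differing pairs are classified with
  precedence i > ii > iii: (i) flanking indel compensating a repeat-length
  difference, (ii) compound repeats redistributing the same total repeat
  length across blocks, (iii) same size and repeats but SNP differences. The
  reported percentage uses allele *copies* that share their size with at
  least one other copy as the denominator; counting distinct size classes
  instead would also be defensible, and copies were chosen because they make
  the percentage a property of the sample rather than of the allele
  spectrum.

## Diversity

Nei's gene diversity is computed from class counts,
`He = n/(n-1) * (1 - sum p_i^2)` by default; the plug-in (biased) form is a
switch, since published tables do not always state which was used. SNP
density is reported per 100 bp of flanking consensus. Note that the unbiased
correction can break the refinement ordering between components, so the
package's refinement property (whole-sequence diversity dominating every
component) is asserted on the plug-in form only.

## Linkage disequilibrium

All pairs of flanking polymorphic sites at a locus are tested with an exact
conditional test: the p-value is the null probability, given the margins, of
tables whose multivariate hypergeometric probability is at most that of the
observed table (the "exact probabilities" criterion). Two routes exist:

* `ld_exact_enumerate()` — complete enumeration, used where the table count
  fits a budget; it is the oracle in the test suite.
* `ld_exact_mcmc()` — a Markov chain over tables with fixed margins (2x2
  subtable rotations, Metropolis acceptance), default 10,000 steps after
  1,000 burn-in. The estimate adds one for the observed table so p is never
  zero, and a batch-means standard error (20 batches) is returned because
  the chain is autocorrelated.

Being discrete and conditional, the exact test is *conservative*: its type-I
rate sits at or just below the nominal level. The calibration suite asserts
exactly that (at-or-below nominal, and not drastically below), rather than
pretending the rate is exactly 5%.

Results are reported in three classes (`P>0.05`, `0.001<P<=0.05`,
`P<=0.001`). The LD-versus-distance Mantel test correlates `-log10(p)` with
bp separation and is skipped below four sites, where only three LD values
exist and a permutation test is meaningless.

## Distances and Mantel concordance

Per component: size distance is the absolute bp difference; repeat distance
is the absolute repeat-count difference (single block) or the Euclidean norm
over blocks (compound); flanking distance counts differing sites, each indel
run once; whole-sequence distance is flanking steps plus `repeat_weight`
times repeat steps (weight 1 at the allele level). "Euclidean" is read as
absolute difference for scalars and the L2 norm for repeat vectors — the
only reading consistent with both uses.

`mantel_test()` reports both the cross-product statistic `Z` and Pearson
`r`, permutes one matrix's labels jointly, and returns a one-tailed
(positive association) add-one p-value; one-tailed matches the convention of
the classical population-genetics toolchain. Zero-variance matrices return a
not-applicable result rather than an error, and that flag propagates through
the concordance report.

## Differentiation: one AMOVA engine, three statistics

For haploid allele copies the among/within partition of squared distances
gives

```
SSD_total  = (1/N)  sum_{i<j} d2_ij          sigma2_w = SSD_within / (N - P)
SSD_within = sum_p (1/N_p) sum_{i<j in p} d2_ij
n'         = (N - sum_p N_p^2 / N) / (P - 1)
sigma2_a   = (SSD_among/(P-1) - sigma2_w) / n'
Phi        = sigma2_a / (sigma2_a + sigma2_w)
```

with significance from permuting alleles among populations (default 1,000
permutations, add-one p). The three classical statistics are the same engine
with different squared distances:

* **FST** — identity distances (0 same class, 1 different): the
  haplotype-frequency view, appropriate under the infinite-allele model.
  Data are haploid allele copies, so the haplotype-level Phi formulation is
  the natural reading of the classical estimator here.
* **RST** — squared size or repeat-count differences: the stepwise-mutation
  view.
* **NST** — mutational step counts (flanking sites, each indel run one
  step): the infinite-site view. For whole amplicons, repeat steps enter
  down-weighted (default `w = 0.05` per repeat step): repeats are roughly an
  order of magnitude richer in alleles than individual SNPs in data of this
  kind, and allowing for unsampled rare alleles a 1:20 richness ratio is a
  reasonable working value. The weight applies per repeat-unit step
  (`w * |delta n|`), not per mutation event — with multi-step mutations the
  two differ, and per-step is what a step-count distance measures.

Step counts enter the engine *as* squared distances (`d2 := steps`), the
convention of molecular AMOVA; a flag squares them instead. When every
inter-class distance is equal, NST collapses onto FST exactly — that
reduction is the engine's correctness anchor in the test suite, alongside a
brute-force double-loop oracle agreeing to 1e-10.

Pairwise population matrices are two-population AMOVAs per pair and locus;
the multi-locus consensus is the element-wise mean. Negative pairwise values
(finite-sample noise around zero) are preserved in reports and floored at
zero only where a tree is built from them.

## Trees

`upgma()` is standard average-linkage agglomeration (heights = distance/2)
with labels sorted lexicographically first, so ties break deterministically.
`consensus_tree()` averages per-locus matrices before clustering — averaging
distances, not reconciling per-locus trees, because a three-locus design
gives far too few trees for a meaningful topological consensus.
`topology_equal()` compares unrooted split sets, ignoring branch lengths and
root placement.

## The simulator

Every stage above is testable against known truth because the package ships
a coalescent simulator of joint SSR + flanking evolution:

* **Genealogy**: Kingman coalescent with haploid scaling (pairwise
  coalescence rate `1/N`), under either a symmetric island model
  (per-lineage migration rate `m`; zero migration with multiple demes is
  rejected since lineages could never coalesce) or a fixed population split
  tree with times in generations. Trees are ultrametric with tips at time 0.
* **Repeats**: per branch and block, Poisson(`mu_ssr` x length) mutations;
  SMM steps of +/-1, or GSM with geometric step magnitudes. Counts reflect
  at one repeat (a step below 1 bounces: 0 -> 2), because a locus with no
  repeats is unobservable as an SSR.
* **Flanking SNPs**: jointly infinite-sites — Poisson(`mu_snp` x flank
  length x tree length) mutations, each on a new site drawn outside indel
  runs, each on a branch chosen proportionally to length. Requesting more
  mutations than free sites is an error (the finite rendering limit).
* **Indels**: Poisson(`mu_indel` x tree length) events, each one new gap run
  with geometric length (mean `indel_mean_bp`), placed entirely within one
  flanking segment, non-overlapping and separated by at least one column so
  each run renders as exactly one codable event. Runs are modelled as
  deletions relative to the rendered consensus; an insertion carried by some
  alleles is alignment-equivalent to a deletion in the others, so this loses
  no generality at the alignment level.
* **Rendering**: the amplicon is laid out as `n_blocks + 1` flanking
  segments interleaved with repeat blocks; each block is the motif repeated
  the tip's count, right-padded with gaps to the widest allele. By
  construction, `decompose_alleles(render_alignment(truth))` recovers the
  true repeat counts and flanking site counts exactly, for every seed — the
  round-trip identity that anchors the whole test suite.

Defaults emulate a realistic sequenced-amplicon study: 4 populations x 25
haploid allele copies, `N = 1000`, one dinucleotide block of 12 repeats, a
150 bp flank, `mu_ssr = 2.5e-3` per block (repeat diversity `theta = 5`),
`mu_snp = 6e-6` per site, `mu_indel = 2e-4` per amplicon, mean indel 8 bp.
These put per-locus flanking SNP counts in the single-to-low-double digits
and indel runs in the single digits, with the repeat process mutating orders
of magnitude faster per locus than any single flanking site — the rate
contrast that makes flanking variation informative about deeper history.
Simulated loci are unlinked (independent genealogies) and there is no
recombination within an amplicon: all sites of a locus share one genealogy,
which is what produces the strong within-locus LD seen in sequenced SSRs.

### What the simulator does *not* emulate

No selection, no sequencing or alignment error, no diploid genotypes (the
unit is the sequenced allele copy), no recombination within the amplicon,
and — importantly — no upper bound on repeat counts. Real microsatellites
saturate: range constraints and homoplasy erode deep phylogenetic signal in
repeat data, which is precisely why repeat-based RST is noisier than
sequence-based NST on deep structure in real data. Under an unbounded
stepwise walk, repeat distances keep tracking deep splits, so in our
split-recovery experiment RST recovers the true grouping nearly as often as
NST. Passing that experiment therefore validates the estimators and the
machinery, not the claim that repeat data are unreliable in nature; the
latter depends on saturation that this generator deliberately leaves out.

## Numerical and reproducibility choices

* Every random procedure takes a seed; the pipeline derives an independent
  sub-seed per stage so stages are individually reproducible, and a rerun
  with the same seed is byte-identical (the manifest records md5 checksums).
* Permutation and MCMC p-values use the add-one convention; they can attain
  `1/(B+1)` but never 0.
* Tie comparisons in permutation counts use a `1e-12` tolerance so exact
  ties count as exceedances rather than depending on floating-point noise.
* Missing states (gap under an indel at a SNP column) are dropped pairwise;
  treating the gap as a fifth state is deliberately not the default, since
  the indel run is already coded as its own site and would be counted twice.
* Monomorphic inputs return zero-valued, flagged results instead of errors
  wherever a zero is well-defined (FST of a monomorphic locus is 0), and
  not-applicable flags where it is not (Mantel r of a constant matrix).

## Problem sizes in the test suite

The statistical checks run at sizes chosen to give comfortable Monte-Carlo
resolution: 5,000 replicates for the pairwise coalescence-time expectation
(5% band), 2,000 for the segregating-sites expectation (5%), 10,000 draws
for the Poisson branch-count check (3%), 200 random tables for
MCMC-versus-enumeration agreement (3 batch-means SEs, 95% coverage), 400
replicates per null-calibration experiment, and 100 replicates of the
three-locus split-recovery experiment (4 x 15 copies, deep 2+2 split at
20,000 generations against 1,000 within pairs). These sizes are the
package's own choices, balancing resolution against a test suite a
maintainer will actually run.

## Known limitations

* Only two-level AMOVA (populations within total); no groups-of-populations
  level, which a 4-population design cannot support meaningfully.
* The LD test conditions on observed margins; no composite-genotype LD for
  unphased diploids, and no r2/D' summaries (significance classes only).
* The homoplasy denominator and the treatment of imperfect alleles are
  conventions (documented above and switchable where sensible); with other
  conventions the headline percentage will shift.
* Input alignments are trusted as given; the package does not re-align.
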