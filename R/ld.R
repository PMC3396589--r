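#' @useDynLib ssrflank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# joint state table of two sites over alleles, dropping pairwise-missing
# alleles and any state left unobserved; NULL if either site is monomorphic
# after removal
.ld_table <- function(states_a, states_b) {
  keep <- !is.na(states_a) & !is.na(states_b)
  a <- factor(states_a[keep])
  b <- factor(states_b[keep])
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NULL)
  unclass(unname(tab))
}

# log hypergeometric probability of a table given margins
.log_table_prob <- function(tab) {
  n <- sum(tab)
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(n + 1) - sum(lgamma(tab + 1))
}

#' Exact test of association by complete enumeration
#'
#' Enumerates all contingency tables with the observed margins and sums the
#' probabilities of tables whose (multivariate hypergeometric) probability is
#' at most that of the observed table — the Fisher "exact probabilities"
#' criterion. Serves as the oracle for the MCMC estimate.
#'
#' @param tab Integer contingency table (matrix).
#' @param max_tables Enumeration budget; an error directs larger problems to
#'   [ld_exact_mcmc()].
#' @return Exact p-value.
#' @export
ld_exact_enumerate <- function(tab, max_tables = 2e5) {
  tab <- as.matrix(tab)
  storage.mode(tab) <- "integer"
  rs <- rowSums(tab); cs <- colSums(tab)
  lp_obs <- .log_table_prob(tab)
  tol <- 1e-9 * (1 + abs(lp_obs))
  r <- nrow(tab); cc <- ncol(tab)
  count <- 0L
  p <- 0
  cur <- matrix(0L, r, cc)
  # fill row by row; within a row, cell by cell
  recurse <- function(i, j, row_left, col_left) {
    if (count > max_tables)
      stop("too many tables to enumerate (> ", max_tables,
           "); use ld_exact_mcmc()")
    if (i == r) {                       # last row fully forced by columns
      cur[r, ] <<- col_left
      count <<- count + 1L
      lp <- .log_table_prob(cur)
      if (lp <= lp_obs + tol) p <<- p + exp(lp)
      return(invisible())
    }
    if (j == cc) {                      # last cell of row is forced
      v <- row_left
      if (v > col_left[cc]) return(invisible())
      cur[i, cc] <<- v
      cl <- col_left; cl[cc] <- cl[cc] - v
      recurse(i + 1L, 1L, rs[i + 1L], cl)
      return(invisible())
    }
    hi <- min(row_left, col_left[j])
    for (v in 0:hi) {
      cur[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i, j + 1L, row_left - v, cl)
    }
  }
  if (r == 1L || cc == 1L) return(1)
  recurse(1L, 1L, rs[1L], cs)
  min(p, 1)
}

#' Exact test of association by Markov chain Monte Carlo
#'
#' Estimates the exact-test p-value for the joint state table of two
#' polymorphic sites by a Markov chain over tables with fixed margins (2x2
#' subtable rotations, Metropolis acceptance). Deterministic given a seed; the
#' add-one rule counts the observed table so the estimate can never be zero.
#'
#' @param states_a,states_b State vectors of the two sites over the same
#'   alleles (`NA` = missing; such alleles are dropped pairwise).
#' @param steps Chain steps after burn-in (default 10000).
#' @param burnin Burn-in steps (default 1000).
#' @param seed Optional RNG seed.
#' @return An object of class `ld_result` with the table, `p`, significance
#'   `class`, `method`, and (when skipped) a `reason`.
#' @export
ld_exact_mcmc <- function(states_a, states_b, steps = 10000L,
                          burnin = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- .ld_table(states_a, states_b)
  if (is.null(tab))
    return(structure(list(table = NULL, p = NA_real_, class = NA_character_,
                          method = "mcmc", steps = steps, seed = seed,
                          skipped = TRUE,
                          reason = "monomorphic after pairwise removal"),
                     class = "ld_result"))
  res <- .ld_mcmc_chain(tab, as.integer(steps), as.integer(burnin))
  structure(list(table = tab, p = res[1L], se = res[3L],
                 class = ld_class(res[1L]),
                 method = "mcmc", steps = steps, seed = seed,
                 skipped = FALSE, reason = NA_character_),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  if (x$skipped) cat("LD test skipped:", x$reason, "\n")
  else cat("LD exact test (", x$method, "): p = ", signif(x$p, 4),
           " [", x$class, "]\n", sep = "")
  invisible(x)
}

#' Three-level significance class for a p-value
#'
#' `P>0.05` (not significant), `0.001<P<=0.05` (significant), `P<=0.001`
#' (highly significant).
#'
#' @param p p-value(s).
#' @param alpha Nominal level separating the first two classes.
#' @return Character vector of class labels.
#' @export
ld_class <- function(p, alpha = 0.05) {
  ifelse(is.na(p), NA_character_,
         ifelse(p > alpha, "P>0.05",
                ifelse(p > 0.001, "0.001<P<=0.05", "P<=0.001")))
}

#' Pairwise linkage disequilibrium among flanking-region sites
#'
#' Tests every unordered pair of retained flanking-region polymorphic sites at
#' one locus. The number of pairs is `choose(k, 2)` for `k` sites; pairs that
#' become monomorphic after pairwise missing-data removal are counted but
#' reported as skipped.
#'
#' @param dec An [decompose_alleles()] result (or an `ssr_sites` object).
#' @param steps,burnin MCMC settings (see [ld_exact_mcmc()]).
#' @param alpha Significance level for the summary count.
#' @param seed Optional seed (one stream drives all pair tests).
#' @param method `"mcmc"` (default), or `"enumerate"` for exact enumeration
#'   where tractable (falls back to MCMC above the budget).
#' @return An object of class `ld_matrix`: `pairs` (long table with `p` and
#'   significance class per pair), `p_matrix`, `n_pairs`, `n_tested`,
#'   `n_significant`, `fraction`.
#' @export
ld_matrix <- function(dec, steps = 10000L, burnin = 1000L, alpha = 0.05,
                      seed = NULL, method = c("mcmc", "enumerate")) {
  method <- match.arg(method)
  sites <- if (inherits(dec, "ssr_sites")) dec else dec$sites
  fr <- sites$table[!sites$table$in_repeat, , drop = FALSE]
  st <- sites$states[, fr$site, drop = FALSE]
  k <- nrow(fr)
  if (!is.null(seed)) set.seed(seed)
  pair_rows <- list()
  pmat <- matrix(NA_real_, k, k, dimnames = list(fr$site, fr$site))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      tab <- .ld_table(st[, i], st[, j])
      if (is.null(tab)) {
        p <- NA_real_; skipped <- TRUE
        reason <- "monomorphic after pairwise removal"
      } else {
        p <- if (method == "enumerate") {
          tryCatch(ld_exact_enumerate(tab),
                   error = function(e)
                     .ld_mcmc_chain(tab, as.integer(steps),
                                    as.integer(burnin))[1L])
        } else {
          .ld_mcmc_chain(tab, as.integer(steps), as.integer(burnin))[1L]
        }
        skipped <- FALSE; reason <- NA_character_
      }
      pmat[i, j] <- pmat[j, i] <- p
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        locus = sites$locus, site_a = fr$site[i], site_b = fr$site[j],
        pos_a = fr$start[i], pos_b = fr$start[j], p = p,
        class = ld_class(p, alpha), skipped = skipped, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(locus = character(0), site_a = character(0),
               site_b = character(0), pos_a = integer(0), pos_b = integer(0),
               p = numeric(0), class = character(0), skipped = logical(0),
               reason = character(0))
  n_pairs <- if (k >= 2L) choose(k, 2L) else 0L
  tested <- pairs[!pairs$skipped, , drop = FALSE]
  n_sig <- sum(tested$p <= alpha)
  structure(list(pairs = pairs, p_matrix = pmat, sites = fr,
                 n_pairs = n_pairs, n_tested = nrow(tested),
                 n_significant = n_sig,
                 fraction = if (n_pairs) n_sig / n_pairs else NA_real_,
                 alpha = alpha, locus = sites$locus),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("LD at '", x$locus, "': ", x$n_significant, " of ", x$n_pairs,
      " site pairs significant at alpha = ", x$alpha,
      if (!is.na(x$fraction)) sprintf(" (%.0f%%)", 100 * x$fraction) else "",
      "\n", sep = "")
  invisible(x)
}

#' Mantel test of LD strength against physical site distance
#'
#' Correlates `-log10(p)` of the pairwise LD tests with the bp separation of
#' the sites. Requires at least 4 sites (3 LD values admit no permutation
#' test); skipped pairs contribute no LD signal (`-log10(1) = 0`).
#'
#' @param ldm An [ld_matrix()] result.
#' @param permutations,seed Passed to [mantel_test()].
#' @return A `mantel_result`, or a skipped stub (with `reason`) for < 4
#'   sites.
#' @export
ld_distance_mantel <- function(ldm, permutations = 999L, seed = NULL) {
  k <- nrow(ldm$sites)
  if (k < 4L)
    return(structure(list(Z = NA_real_, r = NA_real_, p = NA_real_,
                          permutations = permutations, seed = seed,
                          applicable = FALSE,
                          reason = sprintf("only %d LD values", choose(k, 2))),
                     class = "mantel_result"))
  lp <- ldm$p_matrix
  lp[is.na(lp)] <- 1
  ldmat <- -log10(lp)
  diag(ldmat) <- 0
  bp <- abs(outer(ldm$sites$start, ldm$sites$start, "-"))
  dimnames(bp) <- dimnames(ldmat)
  mantel_test(ldmat, bp, permutations = permutations, seed = seed)
}
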