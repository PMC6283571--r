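## Drug-target overlap enrichment: the observed candidate/target overlap
## against a permutation null of equal-size random draws from a gene
## universe, with an exact hypergeometric cross-check.

#' Permutation test of candidate / drug-target gene overlap
#'
#' Draws `|candidates|` genes uniformly without replacement from the
#' universe `n_perm` times and records each draw's overlap with the target
#' list. Fold enrichment = observed overlap / null mean; the one-sided p
#' is the fraction of null overlaps >= observed (optionally with the
#' (count+1)/(n_perm+1) correction). Candidates or targets outside the
#' universe are dropped with a warning.
#'
#' @param candidates,targets,universe Character vectors of gene IDs.
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Integer seed.
#' @param plus_one Use the (count+1)/(n_perm+1) p estimator.
#' @return List of class `drug_enrichment`: n_candidates, n_targets,
#'   n_universe, observed_overlap, null_mean, fold_enrichment,
#'   p_one_sided, p_label (e.g. "<1e-04" when no null draw reaches the
#'   observed overlap), n_permutations, seed, overlapping_genes.
#' @export
overlap_permutation_test <- function(candidates, targets, universe,
                                     n_perm = 10000L, seed = 1L,
                                     plus_one = FALSE) {
  universe <- unique(universe)
  candidates <- unique(candidates)
  targets <- unique(targets)
  drop_c <- setdiff(candidates, universe)
  if (length(drop_c)) {
    warning(length(drop_c), " candidate(s) outside the universe dropped")
    candidates <- intersect(candidates, universe)
  }
  drop_t <- setdiff(targets, universe)
  if (length(drop_t)) {
    warning(length(drop_t), " target(s) outside the universe dropped")
    targets <- intersect(targets, universe)
  }
  if (!length(candidates)) stop("no candidates inside the universe")
  if (!length(targets))
    stop("no targets inside the universe: null mean would be 0")
  overlap_genes <- sort(intersect(candidates, targets))
  res <- .overlap_perm_core(n_candidates = length(candidates),
                            n_targets = length(targets),
                            n_universe = length(universe),
                            observed = length(overlap_genes),
                            n_perm = n_perm, seed = seed,
                            plus_one = plus_one)
  res$overlapping_genes <- overlap_genes
  res
}

#' Count-only overlap permutation test
#'
#' The same permutation null as [overlap_permutation_test()], run from the
#' four counts alone (universe, candidate and target sizes plus the
#' observed overlap) — the mode used to reproduce published enrichment
#' statistics when the underlying gene lists are not distributed.
#'
#' @param n_candidates,n_targets,n_universe,observed Integer counts.
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Integer seed.
#' @param plus_one Use the (count+1)/(n_perm+1) p estimator.
#' @return List of class `drug_enrichment` (no `overlapping_genes`).
#' @export
overlap_permutation_counts <- function(n_candidates, n_targets, n_universe,
                                       observed, n_perm = 10000L,
                                       seed = 1L, plus_one = FALSE) {
  .overlap_perm_core(n_candidates, n_targets, n_universe, observed,
                     n_perm, seed, plus_one)
}

#' @noRd
.overlap_perm_core <- function(n_candidates, n_targets, n_universe,
                               observed, n_perm, seed, plus_one) {
  if (n_perm < 1000L) stop("n_perm must be >= 1000")
  if (observed > min(n_candidates, n_targets) ||
      n_candidates > n_universe || n_targets > n_universe)
    stop("inconsistent counts")
  if (n_targets == 0L) stop("no targets: null mean would be 0")
  set.seed(seed)
  ## genes 1..n_targets of the universe are the targets; each draw counts
  ## how many sampled indices land among them
  null_overlap <- vapply(seq_len(n_perm), function(b)
    sum(sample.int(n_universe, n_candidates) <= n_targets), integer(1L))
  null_mean <- mean(null_overlap)
  n_ge <- sum(null_overlap >= observed)
  p <- if (plus_one) (n_ge + 1) / (n_perm + 1) else n_ge / n_perm
  p_label <- if (n_ge == 0L && !plus_one)
    sprintf("<%g", 1 / n_perm) else format(p, digits = 4L)
  structure(list(n_candidates = n_candidates, n_targets = n_targets,
                 n_universe = n_universe, observed_overlap = observed,
                 null_mean = null_mean,
                 fold_enrichment = observed / null_mean,
                 p_one_sided = p, p_label = p_label,
                 n_permutations = n_perm, seed = seed),
            class = "drug_enrichment")
}

#' Hypergeometric cross-check of the permutation null
#'
#' Closed-form expectation n*K/N of the overlap and the exact
#' hypergeometric upper-tail probability P(X >= observed); the
#' permutation null mean and p converge to these as the number of
#' permutations grows.
#'
#' @param n_candidates,n_targets,n_universe,observed Integer counts.
#' @return List with expected_overlap and tail_p.
#' @export
hypergeometric_check <- function(n_candidates, n_targets, n_universe,
                                 observed) {
  if (observed > min(n_candidates, n_targets) ||
      n_candidates > n_universe || n_targets > n_universe || observed < 0)
    stop("inconsistent counts")
  expected <- n_candidates * n_targets / n_universe
  tail_p <- stats::phyper(observed - 1, n_targets,
                          n_universe - n_targets, n_candidates,
                          lower.tail = FALSE)
  list(expected_overlap = expected, tail_p = tail_p)
}

#' @export
print.drug_enrichment <- function(x, ...) {
  cat(sprintf(
    "Overlap permutation test: %d/%d candidates hit %d targets (universe %d)\n",
    x$observed_overlap, x$n_candidates, x$n_targets, x$n_universe))
  cat(sprintf("  null mean %.4f, fold enrichment %.2f, one-sided p %s (%d permutations)\n",
              x$null_mean, x$fold_enrichment, x$p_label, x$n_permutations))
  invisible(x)
}
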