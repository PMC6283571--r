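## Per-sample immune infiltration scoring by single-sample GSEA: the
## rank-based summed-difference statistic of Barbie et al. Each sample is
## scored independently from the ranks of its own expression vector, so
## scores are exactly invariant to any strictly increasing transform of a
## sample's values.

#' ssGSEA score of one gene set across samples
#'
#' For each sample, genes are ranked by decreasing expression (average
#' ranks for ties). Walking the ranked list, an in-set ECDF weighted by
#' `rank^alpha` (the rank-position value `N - position + 1`, normalized to
#' sum to one over set genes) is accumulated against the uniform
#' out-of-set ECDF; the score is the sum of the running differences over
#' all positions. Set genes absent from the matrix are dropped with a
#' warning.
#'
#' @param expr Genes-by-samples non-negative expression matrix.
#' @param gene_set Character vector of gene IDs.
#' @param alpha Rank weight exponent, >= 0 (0.25 by default, the common
#'   ssGSEA choice).
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(alpha >= 0)
  gene_set <- unique(gene_set)
  absent <- setdiff(gene_set, rownames(expr))
  if (length(absent)) {
    warning(sprintf("%d set gene(s) absent from the matrix dropped",
                    length(absent)))
    gene_set <- setdiff(gene_set, absent)
  }
  n <- nrow(expr)
  nh <- length(gene_set)
  if (nh == 0L) stop("no set genes present in the matrix")
  if (nh == n) stop("gene set covers every gene; out-of-set ECDF undefined")
  in_set <- rownames(expr) %in% gene_set
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    ## descending rank with average ties = n + 1 - ascending average rank
    r_desc <- n + 1 - rank(x, ties.method = "average")
    ## walk order: decreasing expression, gene ID breaks ties
    ord <- order(x, rownames(expr), decreasing = c(TRUE, FALSE),
                 method = "radix")
    hit <- in_set[ord]
    w <- (n - r_desc[ord] + 1)^alpha  # rank-position value^alpha
    p_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    p_out <- cumsum(!hit) / (n - nh)
    sum(p_in - p_out)
  }, numeric(1L))
  stats::setNames(scores, colnames(expr))
}

#' Infiltration scores for a collection of cell-type signatures
#'
#' Applies [ssgsea_score()] per signature. Optionally min-max rescales each
#' cell type's scores across samples to `[0, 1]` (off by default; some
#' published immune-scoring pipelines normalize before median splits, so
#' both behaviors are exposed).
#'
#' @param expr Genes-by-samples expression matrix.
#' @param signatures Named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @param alpha Rank weight exponent.
#' @param rescale If TRUE, min-max rescale each cell type to `[0, 1]`.
#' @return Long data.frame with columns sample_id, cell_type, score.
#' @export
score_cell_types <- function(expr, signatures, alpha = 0.25,
                             rescale = FALSE) {
  if (!length(signatures))
    return(data.frame(sample_id = character(), cell_type = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- lapply(names(signatures), function(nm) {
    s <- ssgsea_score(expr, signatures[[nm]], alpha = alpha)
    if (rescale) {
      rng <- range(s)
      if (diff(rng) > 0) s <- (s - rng[1L]) / diff(rng)
    }
    data.frame(sample_id = names(s), cell_type = nm, score = unname(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract one cell type's scores as a named vector
#'
#' @param score_table Output of [score_cell_types()].
#' @param cell_type Cell type name.
#' @return Named numeric vector (sample_id -> score).
#' @export
get_scores <- function(score_table, cell_type) {
  sub <- score_table[score_table$cell_type == cell_type, , drop = FALSE]
  if (!nrow(sub)) stop("no scores for cell type '", cell_type, "'")
  stats::setNames(sub$score, sub$sample_id)
}
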