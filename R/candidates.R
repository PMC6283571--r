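## Candidate-gene nomination: pool the core enrichment (leading-edge)
## genes of the selected pathways, then keep genes whose group means rise
## sequentially A -> D -> C by at least the fold threshold at each step,
## at a significant three-group FDR.

#' Pool core enrichment genes of selected pathways
#'
#' Union of the leading-edge genes (C-vs-A contrast) of the pathways
#' flagged by [delta_nes_select()], deduplicated and sorted.
#'
#' @param selected Output of [delta_nes_select()] (only rows with
#'   `selected == TRUE` are used) or a character vector of pathway names.
#' @param results_ca [gsea_permutation()] results carrying the
#'   `leading_edge` list-column for the C-vs-A contrast.
#' @return Sorted character vector of gene IDs.
#' @export
collect_core_genes <- function(selected, results_ca) {
  if (is.data.frame(selected))
    selected <- selected$pathway[selected$selected]
  if (!length(selected)) {
    warning("no selected pathways; empty core gene list")
    return(character())
  }
  miss <- setdiff(selected, results_ca$pathway)
  if (length(miss))
    stop("selected pathway(s) absent from the C-vs-A results: ",
         paste(miss, collapse = ", "))
  idx <- match(selected, results_ca$pathway)
  sort(unique(unlist(results_ca$leading_edge[idx])))
}

#' Sequential fold-change / FDR candidate filter
#'
#' For each gene, group means are taken on the normalized expression scale
#' with a pseudocount added before ratios: fold_da = (mean_D + pc) /
#' (mean_A + pc) and fold_cd = (mean_C + pc) / (mean_D + pc). The FDR
#' comes from the three-group ANOVA-like F-test restricted to groups A, D
#' and C, with BH over the supplied gene list. A gene passes when both
#' folds are >= `fold_min` and fdr < `fdr_max`; with
#' `cumulative = TRUE` the alternative reading (overall C/A fold >=
#' `fold_min` with monotone means) is applied instead.
#'
#' @param expr Genes-by-samples non-negative expression matrix.
#' @param groups Named group labels or [stratify_quadrants()] data.frame.
#' @param genes Candidate genes to evaluate (e.g. core enrichment genes).
#' @param fold_min Per-step fold threshold (default 1.5).
#' @param fdr_max FDR threshold (default 0.01).
#' @param pseudocount Added to means before ratios (default 1; RSEM-like
#'   values can be 0).
#' @param cumulative Use the cumulative C/A-fold reading instead of
#'   per-step folds.
#' @return data.frame with gene_id, mean_a, mean_d, mean_c, fold_da,
#'   fold_cd, fdr, passes, missing (TRUE for genes absent from the
#'   matrix).
#' @export
sequential_fold_filter <- function(expr, groups, genes, fold_min = 1.5,
                                   fdr_max = 0.01, pseudocount = 1,
                                   cumulative = FALSE) {
  g <- .group_vector(groups, colnames(expr))
  use <- !is.na(g) & g %in% c("A", "D", "C")
  tab <- table(g[use])
  if (any(!(c("A", "D", "C") %in% names(tab))) || any(tab < 2L))
    stop("groups A, D and C each need >= 2 samples")
  expr_adc <- expr[, use, drop = FALSE]
  g_adc <- g[use]

  present <- genes[genes %in% rownames(expr)]
  absent <- setdiff(genes, present)
  if (!length(present)) stop("none of the supplied genes are in the matrix")

  sub <- expr_adc[present, , drop = FALSE]
  mean_a <- rowMeans(sub[, g_adc == "A", drop = FALSE])
  mean_d <- rowMeans(sub[, g_adc == "D", drop = FALSE])
  mean_c <- rowMeans(sub[, g_adc == "C", drop = FALSE])
  fold_da <- (mean_d + pseudocount) / (mean_a + pseudocount)
  fold_cd <- (mean_c + pseudocount) / (mean_d + pseudocount)

  aov_res <- anova_like_test(sub, g_adc)
  fdr <- aov_res$fdr[match(present, aov_res$gene_id)]

  passes <- if (cumulative) {
    fold_ca <- (mean_c + pseudocount) / (mean_a + pseudocount)
    fold_ca >= fold_min & mean_d >= mean_a & mean_c >= mean_d &
      fdr < fdr_max
  } else {
    fold_da >= fold_min & fold_cd >= fold_min & fdr < fdr_max
  }

  out <- data.frame(gene_id = present, mean_a = mean_a, mean_d = mean_d,
                    mean_c = mean_c, fold_da = fold_da, fold_cd = fold_cd,
                    fdr = fdr, passes = passes, missing = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (length(absent)) {
    warning(length(absent), " gene(s) absent from the matrix")
    out <- rbind(out, data.frame(gene_id = absent, mean_a = NA_real_,
                                 mean_d = NA_real_, mean_c = NA_real_,
                                 fold_da = NA_real_, fold_cd = NA_real_,
                                 fdr = NA_real_, passes = FALSE,
                                 missing = TRUE))
  }
  out[order(out$gene_id), , drop = FALSE]
}
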