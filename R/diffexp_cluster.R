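## Variant-gene selection by a one-way ANOVA-like F-test on log2(x+1)
## across the quadrant groups, Benjamini-Hochberg FDR, Ward clustering of
## patients on the top genes and silhouette-based choice of the cluster
## number. The F-test is fully specified here (defined, not delegated)
## because the input is normalized expression, not raw counts.

#' One-way ANOVA-like F-test per gene across groups
#'
#' For each gene, a one-way ANOVA F statistic on log2(x+1) across the
#' groups, with a BH FDR over all tested genes. Genes with zero within-
#' and between-group variance are reported with p = 1. Groups with a
#' single sample are excluded with a warning.
#'
#' @param expr Genes-by-samples non-negative expression matrix.
#' @param groups Named character vector or `stratify_quadrants()`
#'   data.frame assigning each matrix column to a group.
#' @return data.frame with gene_id, F_statistic, p_value, fdr and one
#'   mean_<group> column per group (log2 scale), in matrix gene order.
#' @export
anova_like_test <- function(expr, groups) {
  g <- .group_vector(groups, colnames(expr))
  keep <- !is.na(g)
  g <- factor(g[keep])
  expr <- expr[, keep, drop = FALSE]
  tab <- table(g)
  if (any(tab < 2L)) {
    warning("group(s) with a single sample excluded: ",
            paste(names(tab)[tab < 2L], collapse = ", "))
    keep2 <- g %in% names(tab)[tab >= 2L]
    g <- droplevels(g[keep2])
    expr <- expr[, keep2, drop = FALSE]
  }
  k <- nlevels(g)
  if (k < 2L) stop("need >= 2 groups with >= 2 samples each")
  y <- log2(expr + 1)
  n <- ncol(y)
  ## vectorized one-way ANOVA over all genes at once
  grand <- rowMeans(y)
  ss_tot <- rowSums((y - grand)^2)
  group_means <- vapply(levels(g), function(lv)
    rowMeans(y[, g == lv, drop = FALSE]), numeric(nrow(y)))
  if (is.null(dim(group_means)))
    group_means <- matrix(group_means, nrow = 1L,
                          dimnames = list(rownames(y), levels(g)))
  n_g <- as.numeric(table(g)[levels(g)])
  ss_between <- as.numeric((group_means - grand)^2 %*% n_g)
  ss_within <- pmax(ss_tot - ss_between, 0)
  df1 <- k - 1L
  df2 <- n - k
  f_stat <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  degenerate <- ss_tot < 1e-12
  f_stat[degenerate] <- 0
  p[degenerate] <- 1
  p[!is.finite(f_stat) & !degenerate] <- 0  # zero within, nonzero between
  out <- data.frame(gene_id = rownames(expr), F_statistic = f_stat,
                    p_value = p, fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  for (lv in levels(g)) out[[paste0("mean_", lv)]] <- group_means[, lv]
  rownames(out) <- NULL
  out
}

#' @noRd
.group_vector <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    g <- stats::setNames(groups$group, groups$sample_id)
  } else g <- groups
  if (is.null(names(g))) {
    if (length(g) != length(sample_ids))
      stop("group vector length does not match sample count")
    names(g) <- sample_ids
  }
  as.character(g[sample_ids])
}

#' Top-k genes by FDR
#'
#' The k smallest-FDR genes; ties broken by smaller p-value, then
#' lexicographic gene ID.
#'
#' @param results Output of [anova_like_test()].
#' @param k Number of genes (k = 0 gives an empty list).
#' @return Character vector of gene IDs.
#' @export
top_k_genes <- function(results, k) {
  if (k > nrow(results)) stop("k exceeds the number of tested genes")
  if (k == 0L) return(character())
  ord <- order(results$fdr, results$p_value, results$gene_id)
  results$gene_id[ord][seq_len(k)]
}

#' Ward clustering of samples on a gene subset
#'
#' Samples are points in log2(x+1) gene space (genes optionally
#' standardized to zero mean/unit variance across samples); pairwise
#' Euclidean distances feed agglomerative Ward linkage (`ward.D2`, heights
#' on the Euclidean scale). Labels are extracted for k = 2..kmax and each
#' k's mean silhouette computed on the same distances.
#'
#' @param expr_subset Genes-by-samples matrix restricted to the clustering
#'   genes (e.g. the top 100).
#' @param kmax Largest cluster number examined (default 10; capped at
#'   n - 1).
#' @param scale_genes Standardize genes before distances (default TRUE).
#' @param log_transform Apply log2(x+1) first (default TRUE).
#' @return List of class `cluster_result`: `hclust`, `dist`, `labels`
#'   (named list "2".."kmax"), `silhouette_mean` (named numeric),
#'   `chosen_k`.
#' @export
ward_cluster <- function(expr_subset, kmax = 10L, scale_genes = TRUE,
                         log_transform = TRUE) {
  if (ncol(expr_subset) < 3L) stop("need >= 3 samples to cluster")
  y <- if (log_transform) log2(expr_subset + 1) else expr_subset
  if (scale_genes) {
    sds <- apply(y, 1L, stats::sd)
    keep <- sds > 0
    y <- (y[keep, , drop = FALSE] - rowMeans(y[keep, , drop = FALSE])) /
      sds[keep]
  }
  d <- stats::dist(t(y), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- seq(2L, min(kmax, ncol(expr_subset) - 1L))
  labels <- lapply(ks, function(k) stats::cutree(hc, k = k))
  names(labels) <- as.character(ks)
  sel <- silhouette_select_k(labels, d)
  structure(list(hclust = hc, dist = d, labels = labels,
                 silhouette_mean = sel$silhouette_mean,
                 chosen_k = sel$chosen_k),
            class = "cluster_result")
}

#' Choose the cluster number by mean silhouette
#'
#' Mean silhouette width per candidate k (singleton clusters contribute 0
#' per the usual convention, with a warning); the chosen k maximizes the
#' mean, ties going to the smaller k.
#'
#' @param labels_by_k Named list (names = k) of integer label vectors.
#' @param distances A `dist` object over the same samples.
#' @return List with `silhouette_mean` (named numeric) and `chosen_k`.
#' @export
silhouette_select_k <- function(labels_by_k, distances) {
  if (max(distances) == 0) stop("degenerate distances: all points identical")
  sil_mean <- vapply(labels_by_k, function(lab) {
    if (any(table(lab) == 1L))
      warning("singleton cluster: silhouette 0 assigned to its point(s)")
    sil <- cluster::silhouette(lab, distances)
    mean(sil[, "sil_width"])
  }, numeric(1L))
  ks <- as.integer(names(labels_by_k))
  best <- which(sil_mean == max(sil_mean))
  chosen <- ks[best[which.min(ks[best])]]
  list(silhouette_mean = sil_mean, chosen_k = chosen)
}

#' Cluster-by-group composition percentages
#'
#' Percentage of each cluster's samples falling in each quadrant group.
#'
#' @param cluster_labels Named/positional cluster labels.
#' @param group_labels Group labels over the same samples.
#' @return data.frame with cluster, group, n, percent.
#' @export
cluster_composition <- function(cluster_labels, group_labels) {
  if (length(cluster_labels) != length(group_labels))
    stop("labelings cover different sample counts")
  tab <- table(cluster = cluster_labels, group = group_labels)
  pct <- prop.table(tab, margin = 1L) * 100
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$percent <- as.data.frame(pct)$Freq
  names(df)[names(df) == "Freq"] <- "n"
  df
}
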