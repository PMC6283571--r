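## Two-group gene set enrichment analysis: signal-to-noise ranking with
## floored standard deviations, the weighted Kolmogorov-Smirnov running
## sum, phenotype-permutation NES and FDR (sign-matched normalized-ES
## ratio estimator), leading-edge extraction, and the NES-difference
## pathway selection rule between two contrasts sharing a reference group.

#' Signal-to-noise gene ranking between two sample groups
#'
#' Per gene, (mu_x - mu_y)/(sigma_x + sigma_y) on log2(x+1) values, with
#' each group's sample standard deviation floored at max(sigma, 0.2|mu|)
#' and at an absolute floor of 0.2 when mu = 0 (the usual GSEA guard
#' against vanishing denominators). Genes are returned in decreasing
#' metric order, ties broken by gene ID.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param group_x,group_y Sample IDs (or column indices) of the two groups;
#'   group_x is the "up" phenotype.
#' @param log_transform Apply log2(x+1) first (default TRUE; set FALSE if
#'   the matrix is already on log scale).
#' @return data.frame with gene_id and metric, sorted decreasing.
#' @export
signal_to_noise <- function(expr, group_x, group_y, log_transform = TRUE) {
  if (length(group_x) < 2L || length(group_y) < 2L)
    stop("need >= 2 samples per group")
  y <- if (log_transform) log2(expr + 1) else expr
  metric <- .snr_metric(y[, group_x, drop = FALSE],
                        y[, group_y, drop = FALSE])
  ord <- order(-metric, rownames(y), method = "radix")
  data.frame(gene_id = rownames(y)[ord], metric = metric[ord],
             stringsAsFactors = FALSE)
}

## SNR on two pre-log matrices sharing rows; vectorized for the
## permutation loop.
#' @noRd
.snr_metric <- function(yx, yy) {
  floor_sd <- function(m, s) {
    s2 <- pmax(s, 0.2 * abs(m))
    s2[m == 0] <- pmax(s[m == 0], 0.2)
    s2
  }
  nx <- ncol(yx); ny <- ncol(yy)
  mx <- rowMeans(yx); my <- rowMeans(yy)
  sx <- sqrt(pmax(rowSums((yx - mx)^2) / (nx - 1), 0))
  sy <- sqrt(pmax(rowSums((yy - my)^2) / (ny - 1), 0))
  (mx - my) / (floor_sd(mx, sx) + floor_sd(my, sy))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: at in-set genes the running sum rises by
#' |metric|^weight normalized over in-set hits; at misses it falls by
#' 1/(N - Nh). ES is the signed maximum deviation; the leading edge
#' (core enrichment genes) is the in-set genes at or before the peak for
#' ES > 0, at or after it for ES < 0.
#'
#' @param ranked data.frame from [signal_to_noise()] (gene_id, metric,
#'   decreasing order) or a named decreasing numeric vector.
#' @param gene_set Character vector of gene IDs.
#' @param weight Metric weight exponent (1 = classic GSEA "weighted";
#'   0 reduces to the unweighted KS statistic on set positions).
#' @return List with `es`, `running` (full running sum), `peak` (position
#'   of max |running|), `leading_edge` (gene IDs).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene_id
    metric <- ranked$metric
  } else {
    genes <- names(ranked)
    metric <- unname(ranked)
  }
  hit <- genes %in% gene_set
  nh <- sum(hit)
  n <- length(genes)
  if (nh == 0L) stop("gene set has no genes in the ranked list")
  if (nh == n) stop("gene set covers the whole ranked list")
  res <- .es_walk(metric, hit, weight)
  leading <- if (res$es >= 0) genes[hit & seq_len(n) <= res$peak]
             else genes[hit & seq_len(n) >= res$peak]
  list(es = res$es, running = res$running, peak = res$peak,
       leading_edge = leading)
}

## Running-sum core shared by the observed and permuted walks.
#' @noRd
.es_walk <- function(metric, hit, weight) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric[hit])^weight
  tot <- sum(w)
  inc <- numeric(n)
  inc[hit] <- if (tot > 0) w / tot else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak], running = running, peak = peak)
}

## ES only, for permutations: metric must already be in walk order.
#' @noRd
.es_only <- function(metric, hit, weight) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric[hit])^weight
  tot <- sum(w)
  inc <- numeric(n)
  inc[hit] <- if (tot > 0) w / tot else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Phenotype-permutation GSEA for a pathway collection
#'
#' For the observed two-group contrast, genes are ranked by signal-to-noise
#' and each pathway scored by the weighted KS statistic. Group labels are
#' then shuffled `n_perm` times, the ranking and every pathway's ES
#' recomputed per shuffle. NES = ES / mean(|permuted ES| of matching
#' sign); the nominal p is the fraction of same-sign permuted ES at least
#' as extreme (floored at 1/n_perm); the FDR is the sign-matched
#' normalized-ES ratio estimator: for a pathway with NES* >= 0 it is the
#' proportion of all permutation NES* >= NES divided by the proportion of
#' observed NES* >= NES (clipped to [0, 1]; mirrored for negative NES).
#'
#' @param expr Genes-by-samples expression matrix.
#' @param group_x,group_y Sample IDs of the contrast (x = "up" phenotype).
#' @param pathways Named list of gene-ID vectors.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed making the permutations reproducible.
#' @param weight ES weight exponent.
#' @param log_transform Apply log2(x+1) before ranking.
#' @param permutation `"phenotype"` (default: shuffle group labels and
#'   re-rank, valid when both groups are reasonably large) or
#'   `"gene_set"` (keep the observed ranking and draw random same-size
#'   gene sets, for contrasts too small to permute).
#' @return data.frame with pathway, size, es, nes, nominal_p, fdr,
#'   n_permutations, seed, and a `leading_edge` list-column.
#' @export
gsea_permutation <- function(expr, group_x, group_y, pathways,
                             n_perm = 1000L, seed = 1L, weight = 1,
                             log_transform = TRUE,
                             permutation = c("phenotype", "gene_set")) {
  permutation <- match.arg(permutation)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (permutation == "phenotype" &&
      min(length(group_x), length(group_y)) < 7L)
    warning("fewer than 7 samples in a group: permutation null is coarse")
  y <- if (log_transform) log2(expr[, c(group_x, group_y)] + 1)
       else expr[, c(group_x, group_y)]
  nx <- length(group_x)
  n_all <- ncol(y)
  genes <- rownames(y)

  keep <- vapply(pathways, function(gs) {
    k <- sum(genes %in% gs)
    k >= 1L && k < length(genes)
  }, logical(1L))
  if (any(!keep))
    warning("pathway(s) with no tested genes skipped: ",
            paste(names(pathways)[!keep], collapse = ", "))
  pathways <- pathways[keep]
  if (!length(pathways)) stop("no scorable pathways")
  hit_sets <- lapply(pathways, function(gs) genes %in% gs)

  score_all <- function(metric) {
    ord <- order(-metric, genes, method = "radix")
    m_ord <- metric[ord]
    vapply(hit_sets, function(h) .es_only(m_ord, h[ord], weight),
           numeric(1L))
  }

  obs_metric <- .snr_metric(y[, seq_len(nx), drop = FALSE],
                            y[, -seq_len(nx), drop = FALSE])
  obs_ord <- order(-obs_metric, genes, method = "radix")
  obs <- lapply(hit_sets, function(h) {
    walk <- .es_walk(obs_metric[obs_ord], h[obs_ord], weight)
    hit_o <- h[obs_ord]
    leading <- if (walk$es >= 0)
      genes[obs_ord][hit_o & seq_along(genes) <= walk$peak]
    else genes[obs_ord][hit_o & seq_along(genes) >= walk$peak]
    list(es = walk$es, leading = leading, size = sum(h))
  })
  obs_es <- vapply(obs, `[[`, numeric(1L), "es")

  set.seed(seed)
  perm_es <- matrix(NA_real_, length(pathways), n_perm,
                    dimnames = list(names(pathways), NULL))
  if (permutation == "phenotype") {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_all, nx)
      metric <- .snr_metric(y[, idx, drop = FALSE],
                            y[, -idx, drop = FALSE])
      perm_es[, b] <- score_all(metric)
    }
  } else {
    ## observed ranking fixed; null = random gene sets of matching size
    m_ord <- obs_metric[obs_ord]
    n_genes <- length(genes)
    sizes <- vapply(hit_sets, sum, integer(1L))
    for (b in seq_len(n_perm)) {
      perm_es[, b] <- vapply(sizes, function(k) {
        h <- logical(n_genes)
        h[sample.int(n_genes, k)] <- TRUE
        .es_only(m_ord, h, weight)
      }, numeric(1L))
    }
  }

  ## per-pathway sign-matched normalization
  pos_mean <- apply(perm_es, 1L, function(e) mean(e[e >= 0]))
  neg_mean <- apply(perm_es, 1L, function(e) mean(abs(e[e < 0])))
  norm_one <- function(e, pm, nm)
    ifelse(e >= 0, e / pm, e / nm)
  nes <- norm_one(obs_es, pos_mean, neg_mean)
  perm_nes <- perm_es / ifelse(perm_es >= 0, pos_mean, neg_mean)

  nominal_p <- vapply(seq_along(obs_es), function(i) {
    e <- obs_es[i]
    perms <- perm_es[i, ]
    same <- if (e >= 0) perms[perms >= 0] else perms[perms < 0]
    if (!length(same)) return(1 / n_perm)
    max(mean(abs(same) >= abs(e)), 1 / n_perm)
  }, numeric(1L))

  all_perm_nes <- as.numeric(perm_nes)
  all_perm_nes <- all_perm_nes[is.finite(all_perm_nes)]
  fdr <- vapply(nes, function(v) {
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(all_perm_nes[all_perm_nes >= 0] >= v)
      den <- mean(nes[nes >= 0] >= v)
    } else {
      num <- mean(all_perm_nes[all_perm_nes < 0] <= v)
      den <- mean(nes[nes < 0] <= v)
    }
    if (is.nan(num)) num <- 0
    min(max(num / den, 0), 1)
  }, numeric(1L))

  out <- data.frame(pathway = names(pathways),
                    size = vapply(obs, `[[`, integer(1L), "size"),
                    es = obs_es, nes = nes, nominal_p = nominal_p,
                    fdr = fdr, n_permutations = n_perm, seed = seed,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- lapply(obs, `[[`, "leading")
  out
}

#' Select differential pathways by the NES difference of two contrasts
#'
#' Restricts to pathways significant (FDR <= `fdr_max`) in the C-vs-A
#' contrast, computes delta = NES(C vs A) - NES(D vs A) and flags
#' pathways with delta >= `delta_min` (or |delta| >= `delta_min` when
#' `absolute = TRUE`). Pathways present in only one result list are
#' excluded with a warning.
#'
#' @param results_ca,results_da Results of [gsea_permutation()] (or any
#'   data.frame with pathway, nes, fdr) for the C-vs-A and D-vs-A
#'   contrasts.
#' @param fdr_max Significance cutoff in the C-vs-A contrast (default
#'   0.05).
#' @param delta_min NES-difference threshold (default 0.25).
#' @param absolute Select on |delta| instead of the positive side.
#' @return data.frame with pathway, nes_ca, fdr_ca, nes_da, delta,
#'   selected.
#' @export
delta_nes_select <- function(results_ca, results_da, fdr_max = 0.05,
                             delta_min = 0.25, absolute = FALSE) {
  only <- c(setdiff(results_ca$pathway, results_da$pathway),
            setdiff(results_da$pathway, results_ca$pathway))
  if (length(only))
    warning("pathway(s) present in only one contrast excluded: ",
            paste(only, collapse = ", "))
  common <- intersect(results_ca$pathway, results_da$pathway)
  ca <- results_ca[match(common, results_ca$pathway), ]
  da <- results_da[match(common, results_da$pathway), ]
  keep <- ca$fdr <= fdr_max
  ca <- ca[keep, ]; da <- da[keep, ]
  delta <- ca$nes - da$nes
  selected <- if (absolute) abs(delta) >= delta_min else delta >= delta_min
  data.frame(pathway = ca$pathway, nes_ca = ca$nes, fdr_ca = ca$fdr,
             nes_da = da$nes, delta = delta, selected = selected,
             stringsAsFactors = FALSE, row.names = NULL)
}
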