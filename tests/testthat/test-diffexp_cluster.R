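test_that("F statistic matches the hand-computed one-way ANOVA", {
  # log2 group values {1,2},{3,4},{5,6}: SSB = 16, SSW = 1.5, F = 16, df (2,3)
  y <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(g1 = 2^y - 1, g2 = rep(1, 6))
  colnames(m) <- paste0("s", 1:6)
  groups <- setNames(rep(c("A", "C", "D"), each = 2), colnames(m))
  res <- anova_like_test(m, groups)
  expect_equal(res$F_statistic[res$gene_id == "g1"], 16)
  expect_equal(res$p_value[res$gene_id == "g1"],
               pf(16, 2, 3, lower.tail = FALSE))
  # constant gene reports p = 1
  expect_equal(res$p_value[res$gene_id == "g2"], 1)
})

test_that("BH FDR is invariant to the order genes are supplied in", {
  set.seed(15)
  m <- toy_matrix(60, 12)
  groups <- setNames(rep(c("A", "B", "C"), each = 4), colnames(m))
  r1 <- anova_like_test(m, groups)
  perm <- sample(nrow(m))
  r2 <- anova_like_test(m[perm, ], groups)
  expect_equal(r2$fdr[match(r1$gene_id, r2$gene_id)], r1$fdr)
  expect_true(all(r1$fdr >= 0 & r1$fdr <= 1))
  # fdr equals p.adjust of the p-vector (step-up definition)
  expect_equal(r1$fdr, p.adjust(r1$p_value, "BH"))
})

test_that("shifted genes concentrate in the top of the FDR ranking", {
  set.seed(33)
  n_genes <- 2000; per_group <- 30
  groups <- setNames(rep(c("A", "B", "C", "D"), each = per_group),
                     sprintf("s%03d", 1:(4 * per_group)))
  m <- matrix(2^(rnorm(n_genes * length(groups)) + 5), n_genes,
              length(groups),
              dimnames = list(sprintf("g%04d", 1:n_genes), names(groups)))
  shifted <- rownames(m)[1:50]
  m[shifted, groups %in% c("C", "D")] <-
    m[shifted, groups %in% c("C", "D")] * 2^1.2
  res <- anova_like_test(m, groups)
  top100 <- top_k_genes(res, 100)
  expect_gte(sum(shifted %in% top100), 45)
})

test_that("top-k selection breaks ties by p then gene ID", {
  res <- data.frame(gene_id = c("gb", "ga", "gc"),
                    F_statistic = 1, p_value = c(0.02, 0.01, 0.01),
                    fdr = c(0.05, 0.05, 0.05))
  expect_identical(top_k_genes(res, 2), c("ga", "gc"))
  expect_identical(top_k_genes(res, 0), character())
  expect_identical(sort(top_k_genes(res, 3)), sort(res$gene_id))
  expect_error(top_k_genes(res, 4), "exceeds")
})

test_that("Ward linkage recovers separated clouds and orders merges", {
  set.seed(4)
  # two clouds far apart
  m <- cbind(matrix(rnorm(40, 0, 0.3), 4, 10),
             matrix(rnorm(40, 8, 0.3), 4, 10))
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:20))
  cl <- ward_cluster(2^m, kmax = 6, scale_genes = FALSE)
  lab <- cl$labels[["2"]]
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[11])
  expect_equal(cl$chosen_k, 2L)
  # merge heights never decrease
  expect_true(all(diff(cl$hclust$height) >= -1e-9))
  # labels at k refine labels at k-1
  for (k in 3:5) {
    fine <- cl$labels[[as.character(k)]]
    coarse <- cl$labels[[as.character(k - 1)]]
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
  # duplicated sample merges first at height zero
  m2 <- m[, c(1, 1, 5, 11, 15)]
  colnames(m2) <- paste0("x", 1:5)
  # singleton clusters at k = 3 legitimately warn; not under test here
  cl2 <- suppressWarnings(ward_cluster(2^m2, kmax = 3, scale_genes = FALSE))
  expect_equal(cl2$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(cl2$hclust$merge[1, ]), c(1, 2))
})

test_that("first Ward merge heights match the brute-force criterion", {
  # 6 points in 3 tight pairs; ward.D2 singleton merge height = distance
  pts <- matrix(c(0, 0.1, 10, 10.05, 20, 20.2), nrow = 1,
                dimnames = list("g1", paste0("s", 1:6)))
  pts <- rbind(pts, g2 = 0)  # need >= 2 genes; second coordinate constant
  cl <- ward_cluster(pts, kmax = 3, scale_genes = FALSE,
                     log_transform = FALSE)
  d <- as.matrix(dist(t(pts)))
  expect_equal(sort(cl$hclust$height[1:3]),
               sort(c(d[1, 2], d[3, 4], d[5, 6])), tolerance = 1e-12)
})

test_that("silhouette selection follows the direct (b-a)/max formula", {
  pts <- matrix(c(0, 1, 10, 11), nrow = 1,
                dimnames = list("g", paste0("p", 1:4)))
  d <- dist(t(rbind(pts, 0)))
  labs <- list(`2` = setNames(c(1, 1, 2, 2), colnames(pts)))
  sel <- silhouette_select_k(labs, d)
  sil <- cluster::silhouette(labs[["2"]], d)
  expect_equal(as.numeric(sil[1, "sil_width"]), (10.5 - 1) / 10.5)
  expect_equal(sel$chosen_k, 2L)
  # all points identical: degenerate
  dd <- dist(matrix(0, 4, 2))
  expect_error(silhouette_select_k(labs, dd), "degenerate")
})

test_that("cluster composition percentages are exact contingencies", {
  comp <- cluster_composition(c(1, 1, 2, 2), c("A", "A", "C", "C"))
  expect_equal(comp$percent[comp$cluster == "1" & comp$group == "A"], 100)
  expect_equal(comp$percent[comp$cluster == "2" & comp$group == "C"], 100)
  # single cluster reproduces overall frequencies
  comp2 <- cluster_composition(rep(1, 4), c("A", "A", "C", "D"))
  expect_equal(comp2$percent[comp2$group == "A"], 50)
})

test_that("patients cluster by pathway shift, clusters align with C/D", {
  sim <- default_cohort()
  tum <- tumor_ids_of(sim)
  g <- sim$truth$groups[tum]
  res <- anova_like_test(sim$expression[, tum], g)
  top <- top_k_genes(res, 100)
  # shifted pathway genes should dominate the most variant genes
  expect_gt(mean(top %in% c(unlist(sim$truth$shifted_sets),
                            sim$gene_sets$B_cells,
                            sim$gene_sets$CD8_T_cells, "CD274")), 0.5)
  cl <- ward_cluster(sim$expression[top, tum], kmax = 10)
  lab <- cl$labels[[as.character(cl$chosen_k)]]
  comp <- cluster_composition(lab, ifelse(g %in% c("C", "D"), "CD", "AB"))
  # some cluster is dominated by the high-B (C/D) patients
  best <- max(comp$percent[comp$group == "CD"])
  expect_gt(best, 70)
})
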