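test_that("signal-to-noise metric applies the floored-sd formula", {
  m <- rbind(gA = c(3, 5, 1, 1),
             gB = c(2, 2, 2, 2),
             gC = c(1, 1, 3, 5))
  colnames(m) <- paste0("s", 1:4)
  r <- signal_to_noise(m, c("s1", "s2"), c("s3", "s4"),
                       log_transform = FALSE)
  # group x {3,5} vs y {1,1}: sd_y floored at 0.2*|1|
  expect_equal(r$metric[r$gene_id == "gA"], 3 / (sqrt(2) + 0.2))
  expect_equal(r$metric[r$gene_id == "gB"], 0)
  # antisymmetry: swapping roles negates every metric, reverses ranking
  r2 <- signal_to_noise(m, c("s3", "s4"), c("s1", "s2"),
                        log_transform = FALSE)
  expect_equal(r2$metric[match(r$gene_id, r2$gene_id)], -r$metric)
  expect_identical(r2$gene_id, rev(r$gene_id))
  expect_error(signal_to_noise(m, "s1", c("s2", "s3")), ">= 2")
})

test_that("enrichment score matches an independent brute-force walk", {
  # single top-ranked gene at weight 1: ES = 1, leading edge = that gene
  ranked <- data.frame(gene_id = paste0("g", 1:10),
                       metric = seq(2, -2, length.out = 10))
  es1 <- enrichment_score(ranked, "g1", weight = 1)
  expect_equal(es1$es, 1)
  expect_identical(es1$leading_edge, "g1")
  # single bottom-ranked gene: negative ES
  expect_lt(enrichment_score(ranked, "g10", weight = 1)$es, 0)

  # random sets agree with the brute-force accumulation, are bounded
  set.seed(19)
  for (i in 1:20) {
    metric <- sort(rnorm(100), decreasing = TRUE)
    genes <- sprintf("g%03d", 1:100)
    gs <- sample(genes, 10)
    for (w in c(0, 1, 2)) {
      es <- enrichment_score(data.frame(gene_id = genes, metric = metric),
                             gs, weight = w)
      run <- es_brute_running(metric, genes %in% gs, w)
      expect_equal(es$running, run)
      expect_equal(abs(es$es), max(abs(run)))
      expect_lte(abs(es$es), 1)
    }
  }
  expect_error(enrichment_score(ranked, "absent"), "no genes")
})

test_that("weight-0 score reduces to the two-sample KS statistic", {
  set.seed(27)
  genes <- sprintf("g%03d", 1:80)
  metric <- sort(rnorm(80), decreasing = TRUE)
  gs <- sample(genes, 12)
  es <- enrichment_score(data.frame(gene_id = genes, metric = metric),
                         gs, weight = 0)
  # direct KS computation on set vs non-set rank positions
  hit <- genes %in% gs
  pos_in <- which(hit); pos_out <- which(!hit)
  diffs <- vapply(seq_along(genes), function(i)
    mean(pos_in <= i) - mean(pos_out <= i), numeric(1))
  ks <- diffs[which.max(abs(diffs))]
  expect_equal(es$es, ks)
})

test_that("the score walk agrees with an established reference", {
  set.seed(55)
  stats <- sort(rnorm(200, sd = 2), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", 1:200)
  idx <- sort(sample(200, 15))
  es <- enrichment_score(data.frame(gene_id = names(stats),
                                    metric = unname(stats)),
                         names(stats)[idx], weight = 1)
  ref <- fgsea::calcGseaStat(stats, selectedStats = idx, gseaParam = 1)
  expect_equal(es$es, ref, tolerance = 1e-9)
})

test_that("phenotype-permutation GSEA is seed-deterministic and null-calibrated", {
  set.seed(61)
  n_genes <- 300
  m <- matrix(2^(rnorm(n_genes * 24) + 5), n_genes, 24,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%02d", 1:24)))
  sets <- lapply(1:12, function(i) sprintf("g%03d", sample(1:n_genes, 15)))
  names(sets) <- sprintf("SET%02d", 1:12)
  gx <- colnames(m)[1:12]; gy <- colnames(m)[13:24]
  r1 <- gsea_permutation(m, gx, gy, sets, n_perm = 150, seed = 5)
  r2 <- gsea_permutation(m, gx, gy, sets, n_perm = 150, seed = 5)
  expect_identical(r1, r2)
  # identically distributed groups: NES magnitudes near 1, few low FDRs
  expect_lt(abs(mean(abs(r1$nes)) - 1), 0.35)
  expect_lte(mean(r1$fdr <= 0.05), 0.1)
  expect_true(all(r1$nominal_p >= 1 / 150))
  expect_true(all(sign(r1$nes) == sign(r1$es)))
  # a pathway with no tested genes is skipped with a warning
  sets$EMPTY <- c("zz1", "zz2")
  expect_warning(gsea_permutation(m, gx, gy, sets, n_perm = 100, seed = 5),
                 "skipped")
  sets$EMPTY <- NULL
  # gene-set permutation mode: same observed ES, deterministic null
  g1 <- gsea_permutation(m, gx, gy, sets, n_perm = 150, seed = 5,
                         permutation = "gene_set")
  g2 <- gsea_permutation(m, gx, gy, sets, n_perm = 150, seed = 5,
                         permutation = "gene_set")
  expect_identical(g1, g2)
  expect_equal(g1$es, r1$es)
  expect_lte(mean(g1$fdr <= 0.05), 0.1)
})

test_that("an embedded pathway attains the top NES and a low FDR", {
  sim <- default_cohort()
  g <- sim$truth$groups
  gi <- split(names(g), g)
  pw <- sim$gene_sets[grep("^PW_", names(sim$gene_sets))]
  r <- gsea_permutation(sim$expression, gi$C, gi$A, pw, n_perm = 200,
                        seed = 31)
  i <- which(r$pathway == "PW_SHIFTED")
  expect_equal(which.max(r$nes), i)
  expect_lte(r$fdr[i], 0.05)
  # leading edge contains the strong-responder core
  expect_true(all(sim$truth$strong_genes$PW_SHIFTED %in%
                    r$leading_edge[[i]]))
})

test_that("NES differences on the published table reproduce the printed column", {
  t4 <- make_table4_fixture()
  ca <- data.frame(pathway = t4$pathway, nes = t4$nes_ca, fdr = t4$fdr_ca)
  da <- data.frame(pathway = t4$pathway, nes = t4$nes_da, fdr = t4$fdr_da)
  d <- delta_nes_select(ca, da, fdr_max = 0.05, delta_min = 0.25)
  expect_equal(d$delta[d$pathway == "Apoptosis"], 0.49)
  expect_true(all(abs(d$delta - t4$delta_printed) <= 0.01 + 1e-9))
  expect_setequal(d$pathway[d$selected],
                  c("Apoptosis", "TNF-a signaling via NF-kB",
                    "Apical surface", "Interferon-a response",
                    "KRAS signaling upregulation"))
  # equal NES in both contrasts: delta 0, never selected
  eq <- data.frame(pathway = "X", nes = 1.5, fdr = 0.01)
  expect_false(delta_nes_select(eq, eq)$selected)
  # mismatched pathway lists: warn and exclude
  expect_warning(delta_nes_select(ca, da[-1, ]), "excluded")
})
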