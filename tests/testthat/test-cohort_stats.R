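test_that("signed-rank test: exact enumeration, symmetric null, extremes", {
  # n = 6, all positive (distinct) differences: one-tailed 1/2^6,
  # two-sided 2/64 by enumeration of all sign patterns
  res <- paired_signed_rank(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p_value, 2 / 64)
  # antisymmetric differences: p near 1
  t_scores <- c(10, 10, 10, 10, 10, 10)
  n_scores <- t_scores + c(1, -1, 2, -2, 3, -3)
  expect_gt(paired_signed_rank(t_scores, n_scores)$p_value, 0.9)
  # uniformly positive shifts attain the minimal exact p for that n
  shifted <- paired_signed_rank(1:8 + seq(0.1, 0.8, by = 0.1), 1:8)
  expect_equal(shifted$p_value, 2 / 2^8)
  expect_error(paired_signed_rank(1:4, 1:4), "degenerate")
})

test_that("tumor infiltration exceeds paired normals on the default cohort", {
  sim <- default_cohort()
  cl <- sim$clinical
  normals <- cl$sample_id[cl$tissue == "normal"]
  tumors <- cl$paired_sample_id[match(normals, cl$sample_id)]
  bs <- ssgsea_score(sim$expression[, c(tumors, normals)],
                     sim$gene_sets$B_cells)
  res <- paired_signed_rank(bs[tumors], bs[normals])
  expect_lt(res$p_value, 0.01)
  expect_gt(median(bs[tumors] - bs[normals]), 0)
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  # fully separated ranks {1,2},{3,4},{5,6}: H = 32/7
  res <- kruskal_wallis_stages(c(1, 2, 3, 4, 5, 6),
                               rep(c("I", "II", "III"), each = 2))
  expect_equal(res$H, 32 / 7)
  expect_equal(res$df, 2)
  expect_equal(nrow(res$pairwise), 3L)
  # identically drawn groups: H small on average
  set.seed(3)
  ps <- replicate(50, kruskal_wallis_stages(
    rnorm(30), rep(c("I", "II", "III"), 10))$p_value)
  expect_gt(mean(ps), 0.3)   # roughly uniform p under the null
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("stage-wise infiltration trend is strongest for the extreme pair", {
  sim <- default_cohort()
  tum <- tumor_ids_of(sim)
  cl <- sim$clinical[match(tum, sim$clinical$sample_id), ]
  bs <- ssgsea_score(sim$expression[, tum], sim$gene_sets$B_cells)
  res <- kruskal_wallis_stages(bs, cl$stage)
  expect_lt(res$p_value, 0.01)
  pw <- res$pairwise
  p_extreme <- pw$p_adjusted[pw$group1 == "I" & pw$group2 == "IV"]
  expect_lt(p_extreme, 0.05)
  # the extreme pair separates at least as clearly as adjacent stages
  p_adjacent <- pw$p_adjusted[(pw$group1 == "I" & pw$group2 == "II") |
                                (pw$group1 == "III" & pw$group2 == "IV")]
  expect_true(all(p_extreme <= p_adjacent))
})

test_that("OLS association: exact fit, null coverage, rank deficiency", {
  set.seed(8)
  b <- rnorm(50); tt <- rnorm(50)
  fit <- suppressWarnings(ols_pdl1_association(2 * b, b, tt))
  expect_equal(fit$estimate[fit$term == "bscore"], 2, tolerance = 1e-8)
  expect_lt(abs(fit$estimate[fit$term == "tscore"]), 1e-8)
  # independent response: coefficients within 2 SE of zero most of the time
  hits <- vapply(1:60, function(s) {
    set.seed(s + 500)
    f <- ols_pdl1_association(rnorm(40), rnorm(40), rnorm(40))
    all(abs(f$estimate[-1]) <= 2 * f$std_error[-1])
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_error(ols_pdl1_association(rnorm(20), b[1:20], b[1:20]),
               "collinear")
})

test_that("quadrant stratification applies the strict-median rule", {
  g <- stratify_quadrants(setNames(c(1, 2, 3, 4), paste0("s", 1:4)),
                          setNames(c(4, 3, 2, 1), paste0("s", 1:4)))
  expect_identical(g$group, c("D", "D", "B", "B"))
  # perfectly rank-correlated variables occupy only A and C
  v <- setNames(as.numeric(1:9), paste0("t", 1:9))
  g2 <- stratify_quadrants(v, v^2)
  expect_setequal(unique(g2$group), c("A", "C"))
  # the rule partitions: every sample in exactly one group
  expect_equal(sum(table(g2$group)), 9L)
  expect_error(stratify_quadrants(rep(1, 6), rnorm(6)), "degenerate")
  # the median tie side is configurable
  v5 <- setNames(c(1, 2, 3, 4, 5), paste0("u", 1:5))
  expect_identical(stratify_quadrants(v5, v5, ties = "low")$group,
                   c("A", "A", "A", "C", "C"))
  expect_identical(stratify_quadrants(v5, v5, ties = "high")$group,
                   c("A", "A", "C", "C", "C"))
})

test_that("positively coupled cohorts fill A and C more than B and D", {
  sim <- default_cohort()
  tum <- tumor_ids_of(sim)
  bs <- ssgsea_score(sim$expression[, tum], sim$gene_sets$B_cells)
  g <- stratify_quadrants(sim$expression["CD274", tum], bs)
  tab <- table(factor(g$group, levels = c("A", "B", "C", "D")))
  expect_equal(sum(tab), length(tum))
  expect_gt(tab[["A"]], tab[["B"]])
  expect_gt(tab[["A"]], tab[["D"]])
  expect_gt(tab[["C"]], tab[["B"]])
  expect_gt(tab[["C"]], tab[["D"]])
})

test_that("KM product-limit and log-rank match hand-computed toys", {
  # single group, times 1, 2+, 3: S(1) = 2/3, S(3) = 0
  sf <- km_logrank(c(1, 2, 3, 1, 2, 3), c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                   rep(c("x", "y"), each = 3))
  cx <- sf$curves[sf$curves$group == "x", ]
  expect_equal(cx$survival[cx$time == 1], 2 / 3)
  expect_equal(cx$survival[cx$time == 3], 0)
  # identical groups: chi-square 0, p = 1
  expect_equal(sf$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(sf$logrank_p, 1)
  expect_equal(sf$mean_survival_difference_days, 0, tolerance = 1e-12)
  # survival curves start at 1 and never increase
  for (gname in c("x", "y")) {
    s <- sf$curves$survival[sf$curves$group == gname]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
})

test_that("log-rank separates high and low infiltration survival", {
  sim <- default_cohort()
  tum <- tumor_ids_of(sim)
  cl <- sim$clinical[match(tum, sim$clinical$sample_id), ]
  b <- sim$truth$b_latent[tum]
  res <- km_logrank(cl$os_days, cl$event,
                    ifelse(b > median(b), "high", "low"))
  expect_lt(res$logrank_p, 0.001)
  # the protective group survives longer on restricted mean
  expect_gt(res$mean_survival[["high"]], res$mean_survival[["low"]])
})

test_that("Cox regression recovers a true hazard ratio of 0.5", {
  est_hr <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 500
    grp <- rep(c(0, 1), each = n / 2)
    tt <- rexp(n, rate = 0.002 * ifelse(grp == 1, 0.5, 1))
    cc <- rexp(n, rate = 0.0002)
    fit <- cox_regression(pmin(tt, cc), tt <= cc,
                          data.frame(arm = ifelse(grp == 1, "high", "low")),
                          mode = "univariate")
    fit$hazard_ratio[1]
  }, numeric(1))
  expect_gte(mean(est_hr >= 0.4 & est_hr <= 0.6), 0.9)
})

test_that("Cox nulls, reference levels and degenerate designs behave", {
  set.seed(77)
  n <- 300
  tt <- rexp(n, 0.01); cc <- rexp(n, 0.002)
  x <- rnorm(n)
  fit <- cox_regression(pmin(tt, cc), tt <= cc, data.frame(x = x),
                        mode = "univariate")
  expect_lt(abs(fit$coef[1]), 2 * fit$se[1])
  # duplicated covariate: rank-deficiency error
  expect_error(cox_regression(pmin(tt, cc), tt <= cc,
                              data.frame(a = x, b = x)),
               "collinear|rank")
  # categorical expansion against stated reference levels
  sim <- default_cohort()
  tum <- tumor_ids_of(sim)
  cl <- sim$clinical[match(tum, sim$clinical$sample_id), ]
  b <- sim$truth$b_latent[tum]
  mv <- cox_regression(cl$os_days, cl$event,
                       data.frame(bcell = ifelse(b > median(b), "high", "low"),
                                  age = cl$age_years, stage = cl$stage,
                                  sex = cl$sex,
                                  egfr_status = cl$egfr_status,
                                  kras_status = cl$kras_status))
  expect_true(all(c("bcellhigh", "stageII", "stageIII", "stageIV",
                    "sexfemale") %in% mv$term))
  # protective B-cell effect: HR below 1, as generated
  expect_lt(mv$hazard_ratio[mv$term == "bcellhigh"], 1)
  expect_true(all(mv$hazard_ratio > 0))
})
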