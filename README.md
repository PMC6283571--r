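# immunoscape

Tumor-infiltrating B cells and the immune checkpoint ligand PD-L1 (CD274)
interact in ways that matter clinically in lung adenocarcinoma: B-cell
infiltration predicts longer overall survival, but that benefit can vanish
in tumors that also express high PD-L1. `immunoscape` is an R package for
dissecting this interaction in bulk tumor transcriptomes. It takes a
normalized genes-by-samples expression matrix, immune cell-type signature
gene sets (GMT), and a per-sample clinical table, and carries them through
a complete, reproducible analysis chain:

1. **Infiltration scoring** — per-sample single-sample GSEA (ssGSEA).
   For each sample, genes are ranked by decreasing expression and the score
   is the summed difference between a rank-weighted in-set ECDF and the
   uniform out-of-set ECDF, with weights `(N - position + 1)^alpha`
   (default `alpha = 0.25`). Scores depend only on within-sample ranks, so
   they are exactly invariant to monotone transforms of each sample.
2. **Quadrant stratification** — tumors split at the median B-cell score
   and median PD-L1 expression into groups A (low/low), B (high PD-L1/low
   B), C (high/high) and D (low PD-L1/high B).
3. **Clinical statistics** — paired Wilcoxon signed-rank (tumor vs matched
   normal), Kruskal–Wallis across stages with Dunn/Nemenyi post-hoc tests,
   multivariate OLS of PD-L1 on infiltration scores, Kaplan–Meier/log-rank
   survival, and Cox proportional-hazards regression (Breslow ties) with
   age, stage, sex and EGFR/KRAS mutation status.
4. **Variant genes and clustering** — one-way ANOVA-like F-test on
   log2(x+1) per gene across the quadrant groups with Benjamini–Hochberg
   FDR; Ward clustering of patients on the top-100 genes; silhouette-based
   choice of the cluster number (k = 2..10).
5. **Two-group GSEA** — signal-to-noise ranking
   `(mu_x - mu_y) / (sigma_x + sigma_y)` with floored standard deviations,
   the weighted Kolmogorov–Smirnov enrichment score, phenotype-permutation
   NES and FDR (sign-matched normalized-ES ratio estimator), and
   leading-edge (core enrichment) extraction.
6. **ΔNES pathway selection** — pathways significant in the C-vs-A
   contrast (FDR ≤ 0.05) whose NES exceeds the D-vs-A NES by ≥ 0.25.
7. **Candidate genes** — core enrichment genes whose group means rise
   sequentially A → D → C by ≥ 1.5-fold at each step (pseudocount 1) at a
   three-group FDR < 0.01.
8. **Drug-target enrichment** — overlap of the candidates with a
   drug-target gene list against a permutation null of random same-size
   draws from a gene universe, reported as fold enrichment
   (observed / null mean) with a one-sided permutation p and an exact
   hypergeometric cross-check.

A synthetic cohort generator (`simulate_cohort`) produces TCGA-like data
with known ground truth — latent infiltration factors, a PD-L1/B-cell
coupling, proportional-hazards survival, and an embedded group-ordered
pathway — so every stage can be validated without any external download.

## Worked example

```r
library(immunoscape)
sim <- simulate_cohort(cohort_params(seed = 7))      # 479 tumors + 31 normals
tumors <- sim$clinical$sample_id[sim$clinical$tissue == "tumor"]

bscore <- ssgsea_score(sim$expression[, tumors], sim$gene_sets$B_cells)
groups <- stratify_quadrants(sim$expression["CD274", tumors], bscore)
table(groups$group)
#>   A   B   C   D
#> 144  96 143  96
```

The four quadrants fill in the characteristic pattern of a positively
coupled cohort: the concordant groups A and C are larger than B and D.
High B-cell infiltration is protective by construction:

```r
cl <- sim$clinical[match(tumors, sim$clinical$sample_id), ]
km <- km_logrank(cl$os_days, cl$event,
                 ifelse(bscore > median(bscore), "high", "low"))
#> log-rank chi2 = 88.9, p = 4.1e-21
#> restricted mean survival: high 1479 vs low 433 days
```

The embedded pathway is recovered by the GSEA/ΔNES stage and its
strong-responder genes survive the sequential fold filter:

```r
gi <- split(groups$sample_id, groups$group)
pw <- sim$gene_sets[grep("^PW_", names(sim$gene_sets))]
ca <- gsea_permutation(sim$expression, gi$C, gi$A, pw, n_perm = 1000, seed = 7)
da <- gsea_permutation(sim$expression, gi$D, gi$A, pw, n_perm = 1000, seed = 8)
sel <- delta_nes_select(ca, da)
sel[sel$selected, c("pathway", "nes_ca", "nes_da", "delta")]
#>      pathway   nes_ca   nes_da     delta
#> 1 PW_SHIFTED 2.938201 2.343645 0.5945561

core <- collect_core_genes(sel, ca)
cand <- sequential_fold_filter(sim$expression[, tumors],
                               setNames(groups$group, groups$sample_id), core)
cand[cand$passes, c("gene_id", "fold_da", "fold_cd", "fdr")]
#>          gene_id  fold_da  fold_cd          fdr
#> 4 PW_SHIFTED_004 1.535214 1.559478 6.182815e-19
#> 9 PW_SHIFTED_009 1.721798 1.600528 9.740829e-25
```

Here `fold_da` and `fold_cd` are the pseudocount-adjusted mean ratios of
the A→D and D→C steps; both passers belong to the embedded pathway's
strong core, and none of the unshifted genes pass. `run_pipeline()` wires
all eight stages together from one (YAML-able) config and writes
per-stage TSV/JSON outputs plus a manifest of every threshold and seed
applied.

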