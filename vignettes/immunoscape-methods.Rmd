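---
title: "Methods and design of the immunoscape pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the immunoscape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(immunoscape)
```

# Scope and model

`immunoscape` analyses bulk tumor transcriptomes for the interplay of
B-cell infiltration and PD-L1 (CD274) expression. The pipeline assumes a
genes-by-samples matrix of non-negative, already-normalized expression
(RSEM-like units). It never re-normalizes; stages that need a log scale
apply `log2(x + 1)` internally. Gene identity is exact string matching —
no alias resolution.

The statistical chain is: per-sample ssGSEA infiltration scores →
median-quadrant stratification (A = low PD-L1/low B, B = high/low,
C = high/high, D = low/high) → survival and clinical statistics →
variant-gene clustering → two-group GSEA of the C-vs-A and D-vs-A
contrasts → ΔNES pathway selection → sequential fold-change candidate
filter → drug-target overlap enrichment. Group B is carried through
stratification and survival but excluded from the GSEA and candidate
stages, which compare the two high-B groups (C, D) against the low/low
reference A.

# The ssGSEA statistic

For sample *j*, genes are ranked by decreasing expression with average
ranks for ties. Walking the ranked list of *N* genes, the score
accumulates the difference between an in-set ECDF weighted by
`(N - position + 1)^alpha` (normalized over the set's genes) and the
uniform ECDF of out-of-set genes; the score is the sum of the running
differences over all *N* positions. This is the summed-difference
("Barbie-style") single-sample statistic. Choices:

* `alpha = 0.25` by default, the value commonly used for ssGSEA scoring.
* Tie handling by average ranks makes the score independent of input
  gene order; the walk itself breaks exact ties deterministically by gene
  ID.
* Because only within-sample ranks enter, any strictly increasing
  transform of one sample's values leaves its score unchanged — the test
  suite asserts this exactly.
* No cross-sample normalization by default. Published immune-scoring
  pipelines sometimes min–max rescale each cell type before median
  splits; `score_cell_types(..., rescale = TRUE)` exposes that behavior,
  and because min–max rescaling is monotone it cannot change who falls
  above or below the median.

# Quadrant stratification

"High" means strictly above the median computed over all tumor samples,
so for odd *n* both sides are non-empty; the tie side is configurable
(`ties = "high"` counts median-equal samples as high). The rule
partitions: every sample with both values lands in exactly one group.

# Survival and clinical statistics

Kaplan–Meier curves, the log-rank test and Cox regressions delegate to
the `survival` package; the module adds the domain contracts (group
handling, warnings for event-free groups, reference levels, error on
rank-deficient or separated designs). Specific choices:

* **Cox ties**: Breslow handling, adequate for day-granularity survival
  data and the simplest well-defined partial likelihood.
* **Reference levels**: stage I, male, non-mutation, "low" for score
  dichotomies — so hazard ratios read as risk relative to the baseline
  patient.
* **Mean survival difference**: the restricted mean (area under each KM
  curve up to the largest observed time). A difference of medians is the
  main alternative; the restricted mean is always defined, also when a
  curve never crosses 0.5.
* **Paired tumor/normal comparison**: Wilcoxon signed-rank on matched
  pairs (exact null for ≤ 25 informative pairs, normal approximation with
  continuity correction above; zero differences dropped). An unpaired
  rank-sum variant is exposed separately for unmatched designs.
* **Stage-wise comparisons**: tie-corrected Kruskal–Wallis, followed by
  pairwise Dunn rank tests with a Tukey-style familywise adjustment in
  the Nemenyi form (`q = |z|·sqrt(2)` against the studentized range
  distribution with infinite df). "Tukey's method after Kruskal–Wallis"
  is not a uniquely defined procedure; this interpretation keeps the
  rank-based post-hoc aligned with the omnibus test while retaining a
  familywise adjustment of the Tukey type.

# Variant genes and clustering

The variant-gene stage is a fully specified one-way ANOVA F-test on
`log2(x + 1)` per gene across the quadrant groups, with
Benjamini–Hochberg FDR over all tested genes. A count-model
quasi-likelihood test would be inappropriate here because the input is
normalized expression, not raw counts; defining the test explicitly also
makes it exactly reproducible. Zero-variance genes report p = 1. The
top-k selection orders by FDR, then p, then gene ID — fully
deterministic under ties.

Patients are clustered on the top 100 genes: Euclidean distances between
samples on the log2 scale with genes standardized to zero mean/unit
variance (row scaling is the heat-map convention that keeps
high-magnitude genes from dominating the metric; `scale_genes = FALSE`
disables it), Ward linkage (`ward.D2`, heights on the distance scale),
and the mean silhouette — on the same distances — selecting k from
2..10, ties to the smaller k. Singleton clusters contribute silhouette 0
by the usual convention, with a warning; identical points make the
silhouette undefined and raise an error.

# Two-group GSEA

Genes are ranked by signal-to-noise on `log2(x + 1)`:
`(mu_x - mu_y) / (sigma_x + sigma_y)` with each group's sample SD floored
at `max(sigma, 0.2·|mu|)` and at 0.2 when the mean is 0 — the standard
guard against near-zero denominators. The enrichment score is the
weighted Kolmogorov–Smirnov statistic: hits advance the running sum by
`|metric|^weight` (normalized over hits), misses retreat by
`1/(N - Nh)`; ES is the signed maximum deviation, and the leading edge
(core enrichment genes) comprises the in-set genes at or before the peak
for positive ES (at or after for negative). With `weight = 0` the
statistic reduces to the classical two-sample KS statistic on set
positions, which the tests verify against a direct computation. The
weight default is 1 (the "weighted" GSEA standard).

Significance comes from phenotype permutation: group labels are shuffled
`n_perm` times (1000 by default) and the full ranking and every
pathway's ES recomputed per shuffle. Then:

* `NES = ES / mean(|permuted ES| of the same sign)`, per pathway;
* the nominal p is the same-sign permutation tail, floored at
  `1/n_perm`;
* the FDR is the sign-matched normalized-ES ratio estimator: for a
  pathway with positive NES, the proportion of all permutation NES above
  it divided by the proportion of observed NES above it, clipped to
  [0, 1] (mirrored for negative NES).

Phenotype permutation is the appropriate null when both groups are large
(here roughly 95–145 samples); for small contrasts a gene-set
permutation mode keeps the observed ranking and draws random same-size
gene sets instead (`permutation = "gene_set"`).

The ΔNES selection restricts to pathways with C-vs-A FDR ≤ 0.05 and
flags those with `NES(C:A) − NES(D:A) ≥ 0.25`. The one-sided threshold
is the primary semantics because the selection targets pathways *more*
activated with PD-L1 present; an absolute-value variant
(`absolute = TRUE`) is exposed for symmetric screening.

# Candidate genes and drug-target enrichment

Core enrichment genes of the selected pathways (C-vs-A leading edges,
deduplicated) enter the sequential fold filter: group means on the
normalized scale with pseudocount 1 (RSEM-like values can be 0), and a
gene passes when both steps A→D and D→C are ≥ 1.5-fold and the
three-group (A, D, C) ANOVA FDR over the candidate list is < 0.01.
"Sequential" is read as *each step* ≥ 1.5-fold; the cumulative
alternative (overall C/A ≥ 1.5 with monotone means) is exposed via
`cumulative = TRUE`. The FDR is computed over the supplied candidate
list rather than genome-wide, since the filter is a confirmation step on
genes already nominated by enrichment.

The drug-target stage counts the overlap of passing candidates with a
user-supplied target list and compares it against `n_perm` (default
10^4) uniform draws of the same number of genes from the universe
(without replacement): fold enrichment = observed / null mean, one-sided
p = tail count / `n_perm` (the `(count+1)/(n_perm+1)` estimator is a
flag). The hypergeometric closed form (`expectation n·K/N`, exact upper
tail) is provided as an analytic cross-check; the permutation null
converges to it, which the tests assert at 10^5 draws within 3
Monte-Carlo SE. A count-only mode reproduces published statistics when
the underlying lists are not available. Candidates and targets are both
drawn from the full universe; excluding candidates from the target pool
first would be a different (slightly conservative) null.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a
lung-adenocarcinoma cohort of 479 annotated tumors plus 31 paired
normals (510 expression profiles), with 2000 genes at the package's
working scale — large enough for a stable permutation null and small
enough that the full test suite runs in well under a minute:

* **Expression**: antilog of Gaussian log2 expression with gene-specific
  baselines (`N(5, 1)`) and per-gene noise SD 1, a typical bulk-tumor
  dispersion. Log-normal values, not negative-binomial counts, because
  the pipeline's contract is normalized expression.
* **Infiltration**: latent B and T factors per tumor (correlated 0.5);
  signature genes shift by `infiltration_effect × latent` (default 1
  log2-fold per latent SD). Paired normals sit `normal_b_shift = 1` SD
  below their tumor — tumors are the infiltrated tissue, giving the
  paired signed-rank test a positive control.
* **PD-L1**: `5 × B-latent + N(0, 15)`, shifted non-negative and stored
  as the reserved gene CD274 (excluded from all signatures to avoid
  score leakage). The noise level sets the PD-L1/B correlation near 0.3,
  which reproduces the roughly 60/40 split between concordant (A, C) and
  discordant (B, D) quadrants seen in real cohorts of this kind.
* **Survival**: exponential times with hazard
  `h0·exp(log(0.5)·B + log(1.5)·(stage − 1))`, baseline 1/1000 per day,
  independent exponential censoring at 1/1500 per day — proportional
  hazards by construction, so Cox recovery is a calibration check, not a
  robustness claim.
* **Stage**: thinned against the B latent (coefficient 0.5; higher
  infiltration, earlier stage) and cut at population quantiles into
  I–IV with realistic occupancy (45/25/18/12%).
* **Embedded pathway**: heterogeneous by design. Ten strong-responder
  genes rise 1.6-fold at each step A→D→C; forty mild responders rise
  1.35-fold only in C. Uniform strong folds across a whole set would
  saturate |ES| near 1 in *both* contrasts, and the NES difference would
  then be governed by permutation-null width (which differs with group
  size), not by effect order. The heterogeneous design keeps the set's
  NES in the moderate range where the C-vs-A contrast cleanly exceeds
  D-vs-A, while the strong core still passes the per-step 1.5-fold
  filter — mirroring how real leading edges concentrate the strong
  responders of a mildly enriched set. Five unshifted 30-gene decoy
  pathways provide the negative control.

What the generator does *not* emulate: batch effects, library-size
artifacts, count-level mean–variance coupling, correlated co-expression
modules beyond the planted factors, missing clinical fields, or
informative censoring. Green tests therefore demonstrate correctness of
the statistical machinery under the generative model, not robustness to
every failure mode of real cohort data.

# Numerical choices and degenerate inputs

* All rank orderings break exact ties deterministically (gene ID, then
  position); repeated runs under one seed are byte-identical, which the
  pipeline tests assert on the emitted files.
* Nominal GSEA p-values floor at `1/n_perm`; FDR ratios clip to [0, 1].
* The ANOVA F-test reports p = 1 for zero-variance genes and p = 0 for
  zero within-group variance with distinct means.
* Degenerate stratification (constant PD-L1 or B score), empty gene
  sets, sets covering the whole matrix, all-zero paired differences,
  rank-deficient regression designs and suspected Cox separation
  (|coefficient| > 15) all raise errors naming the condition.
* Results tables print floats at 6 significant digits sorted by primary
  key, so two runs on the same inputs diff clean.

# Problem sizes

The shipped tests run the full default cohort (479 tumors, 2000 genes)
for the end-to-end chain with 200-permutation GSEA, 100 Cox-recovery
replicates at n = 500, and 10^5-draw permutation-vs-hypergeometric
convergence checks — about 15 seconds total on one core. The pipeline
default of 1000 GSEA permutations and 10^4 drug-enrichment draws matches
the published analysis settings and runs in seconds on a cohort of this
size.

# Known limitations

* ssGSEA scores are comparable across samples only under a shared
  normalization; the package trusts its input's normalization.
* The ΔNES statistic inherits the permutation-null width of each
  contrast; with strongly unbalanced groups, differences in NES partly
  reflect group size. Interpreting ΔNES assumes similar null widths —
  reasonable here, where the reference group A is shared.
* Exact gene-ID matching means mixed identifier schemes must be resolved
  upstream.
* The candidate FDR is computed over the nominated gene list; it is a
  confirmation-step FDR, not a genome-wide discovery FDR.
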