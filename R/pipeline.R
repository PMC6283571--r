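## End-to-end orchestration: infiltrate -> stratify -> survival -> cluster
## -> GSEA (C:A and D:A) -> NES-difference selection -> candidate filter ->
## drug-target enrichment, from one config, with per-stage TSV/JSON outputs
## and a manifest recording every threshold and seed actually applied.

#' Default pipeline configuration
#'
#' Thresholds default to the published analysis settings: GSEA FDR 0.05,
#' NES difference 0.25, sequential fold 1.5, candidate FDR 0.01, top 100
#' variant genes, up to 10 clusters, 1000 GSEA permutations and 10^4
#' drug-enrichment permutations.
#'
#' @param expression,clinical,signatures,pathways Paths to the expression
#'   TSV, clinical TSV, immune-signature GMT and pathway GMT.
#' @param targets Optional path to a drug-target gene list (one ID per
#'   line); NULL skips the drug-enrichment stage.
#' @param universe Optional path to a universe gene list; defaults to the
#'   expression matrix's genes.
#' @param pdl1_gene PD-L1 gene ID in the matrix.
#' @param bcell_signature,tcell_signature Signature names in the GMT.
#' @param fdr_gsea,delta_nes,fold,fdr_candidates,top_genes,kmax,
#'   n_perm_gsea,n_perm_drug,alpha Stage parameters.
#' @param seed Integer seed for every permutation stage.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, signatures, pathways,
                            targets = NULL, universe = NULL,
                            pdl1_gene = "CD274",
                            bcell_signature = "B_cells",
                            tcell_signature = "CD8_T_cells",
                            fdr_gsea = 0.05, delta_nes = 0.25,
                            fold = 1.5, fdr_candidates = 0.01,
                            top_genes = 100L, kmax = 10L,
                            n_perm_gsea = 1000L, n_perm_drug = 10000L,
                            alpha = 0.25, seed = 1L) {
  cfg <- as.list(environment())
  for (nm in c("fdr_gsea", "delta_nes", "fold", "fdr_candidates",
               "top_genes", "kmax", "n_perm_gsea", "n_perm_drug", "alpha"))
    if (cfg[[nm]] <= 0) stop("threshold '", nm, "' must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order, writing per-stage outputs under
#' `out_dir` (scores.tsv, groups.tsv, km.tsv, logrank.json, cox.tsv,
#' variant_genes.tsv, clusters.tsv, silhouette.tsv, gsea_CA.tsv,
#' gsea_DA.tsv, delta_nes.tsv, candidates.tsv, drug_enrichment.json) and
#' a manifest.json recording thresholds, seeds and completed stages. Any
#' stage failure aborts with the stage name; prior outputs are preserved.
#' Group B samples are carried through stratification and survival but
#' excluded from the GSEA and candidate stages.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with every stage's in-memory result plus the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "immunoscape",
                   version = as.character(utils::packageVersion("immunoscape")),
                   thresholds = config[c("fdr_gsea", "delta_nes", "fold",
                                         "fdr_candidates", "top_genes",
                                         "kmax", "n_perm_gsea",
                                         "n_perm_drug", "alpha")],
                   seed = config$seed, stages = character())
  res <- list()
  stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out
  }

  expr <- read_expression_tsv(config$expression)
  clinical <- read_clinical_tsv(config$clinical)
  signatures <- read_gmt(config$signatures)
  pathways <- read_gmt(config$pathways)

  tumor_ids <- intersect(clinical$sample_id[clinical$tissue == "tumor"],
                         colnames(expr))
  if (length(tumor_ids) < 4L) stop("fewer than 4 tumor samples")

  ## 1. infiltration scoring
  res$scores <- stage("infiltrate", function() {
    sc <- score_cell_types(expr, signatures, alpha = config$alpha)
    write_results_table(sc, file.path(out_dir, "scores.tsv"))
    sc
  })

  ## 2. quadrant stratification over tumor samples
  res$groups <- stage("stratify", function() {
    if (!config$pdl1_gene %in% rownames(expr))
      stop("PD-L1 gene '", config$pdl1_gene, "' absent from the matrix")
    pdl1 <- expr[config$pdl1_gene, tumor_ids]
    bsc <- get_scores(res$scores, config$bcell_signature)[tumor_ids]
    grp <- stratify_quadrants(pdl1, bsc)
    write_results_table(grp, file.path(out_dir, "groups.tsv"))
    grp
  })
  gvec <- stats::setNames(res$groups$group, res$groups$sample_id)

  ## 3. survival: KM/log-rank across quadrant groups + Cox
  res$survival <- stage("survival", function() {
    cl <- clinical[match(tumor_ids, clinical$sample_id), ]
    ok <- !is.na(cl$os_days) & !is.na(cl$event)
    cl <- cl[ok, ]
    grp <- gvec[cl$sample_id]
    km <- km_logrank(cl$os_days, cl$event, grp)
    write_results_table(km$curves, file.path(out_dir, "km.tsv"))
    jsonlite::write_json(
      list(chi2 = km$logrank_chi2, p = km$logrank_p, df = km$df,
           restricted_mean_survival = as.list(km$mean_survival)),
      file.path(out_dir, "logrank.json"), auto_unbox = TRUE, digits = NA)
    bsc <- get_scores(res$scores, config$bcell_signature)[cl$sample_id]
    b_level <- ifelse(bsc > stats::median(bsc), "high", "low")
    covs <- data.frame(bcell = b_level, age = cl$age_years,
                       stage = cl$stage, sex = cl$sex,
                       egfr_status = cl$egfr_status,
                       kras_status = cl$kras_status)
    cx <- cox_regression(cl$os_days, cl$event, covs, mode = "multivariate")
    write_results_table(cx, file.path(out_dir, "cox.tsv"))
    list(km = km, cox = cx)
  })

  ## 4. variant genes + Ward clustering + silhouette
  res$cluster <- stage("cluster", function() {
    vg <- anova_like_test(expr[, tumor_ids, drop = FALSE], gvec)
    write_results_table(vg, file.path(out_dir, "variant_genes.tsv"))
    top <- top_k_genes(vg, min(config$top_genes, nrow(vg)))
    cl <- ward_cluster(expr[top, tumor_ids, drop = FALSE],
                       kmax = config$kmax)
    lab <- cl$labels[[as.character(cl$chosen_k)]]
    write_results_table(
      data.frame(sample_id = tumor_ids, cluster = lab,
                 group = gvec[tumor_ids]),
      file.path(out_dir, "clusters.tsv"))
    write_results_table(
      data.frame(k = as.integer(names(cl$silhouette_mean)),
                 mean_silhouette = cl$silhouette_mean,
                 chosen = as.integer(names(cl$silhouette_mean)) ==
                   cl$chosen_k),
      file.path(out_dir, "silhouette.tsv"))
    cl
  })

  ## 5-6. GSEA contrasts C:A and D:A (group B excluded) + selection
  grp_ids <- split(res$groups$sample_id, res$groups$group)
  res$gsea_ca <- stage("gsea_CA", function() {
    r <- gsea_permutation(expr, grp_ids$C, grp_ids$A, pathways,
                          n_perm = config$n_perm_gsea, seed = config$seed)
    write_results_table(r[, setdiff(names(r), "leading_edge")],
                        file.path(out_dir, "gsea_CA.tsv"))
    r
  })
  res$gsea_da <- stage("gsea_DA", function() {
    r <- gsea_permutation(expr, grp_ids$D, grp_ids$A, pathways,
                          n_perm = config$n_perm_gsea,
                          seed = config$seed + 1L)
    write_results_table(r[, setdiff(names(r), "leading_edge")],
                        file.path(out_dir, "gsea_DA.tsv"))
    r
  })
  res$delta <- stage("delta_nes", function() {
    d <- delta_nes_select(res$gsea_ca, res$gsea_da,
                          fdr_max = config$fdr_gsea,
                          delta_min = config$delta_nes)
    write_results_table(d, file.path(out_dir, "delta_nes.tsv"))
    d
  })

  ## 7. candidate genes
  res$candidates <- stage("candidates", function() {
    core <- collect_core_genes(res$delta, res$gsea_ca)
    cand <- if (length(core))
      sequential_fold_filter(expr[, tumor_ids, drop = FALSE], gvec, core,
                             fold_min = config$fold,
                             fdr_max = config$fdr_candidates)
    else data.frame()
    write_results_table(cand, file.path(out_dir, "candidates.tsv"))
    cand
  })

  ## 8. drug-target enrichment
  if (!is.null(config$targets)) {
    res$drug <- stage("drug_enrich", function() {
      targets <- readLines(config$targets, warn = FALSE)
      targets <- targets[nzchar(targets)]
      universe <- if (!is.null(config$universe)) {
        u <- readLines(config$universe, warn = FALSE)
        u[nzchar(u)]
      } else rownames(expr)
      passing <- res$candidates$gene_id[res$candidates$passes %in% TRUE]
      de <- overlap_permutation_test(passing, targets, universe,
                                     n_perm = config$n_perm_drug,
                                     seed = config$seed)
      jsonlite::write_json(unclass(de),
                           file.path(out_dir, "drug_enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      de
    })
  }
  res$manifest <- manifest
  invisible(res)
}
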