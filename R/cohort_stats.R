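## Clinical statistics: paired tumor/normal comparison, stage-wise trends,
## the PD-L1 ~ infiltration regression, median-quadrant stratification,
## Kaplan-Meier/log-rank and Cox proportional hazards. Survival machinery
## is delegated to the survival package (Breslow tie handling for Cox).

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired scores (e.g. tumor vs matched
#' normal infiltration). Zero differences are dropped; the null is exact
#' for n <= 25 pairs (when no ties in |differences|), normal approximation
#' with continuity correction above.
#'
#' @param tumor_scores,normal_scores Equal-length paired numeric vectors.
#' @return List with `statistic` (V), `p_value`, `n_pairs` (after dropping
#'   zero differences).
#' @export
paired_signed_rank <- function(tumor_scores, normal_scores) {
  if (length(tumor_scores) != length(normal_scores))
    stop("paired vectors must have equal length")
  d <- tumor_scores - normal_scores
  d <- d[d != 0]
  if (!length(d)) stop("degenerate pairing: all differences zero")
  if (length(d) < 5L) warning("fewer than 5 non-zero pairs")
  ht <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = "two.sided",
    exact = length(d) <= 25L, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_pairs = length(d))
}

#' Unpaired Wilcoxon rank-sum test (optional alternative)
#'
#' @param x,y Numeric vectors for the two groups.
#' @return List with `statistic` (W) and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Kruskal-Wallis across stages with Dunn/Nemenyi post-hoc
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value, followed by
#' pairwise Dunn rank comparisons with a Tukey-style familywise adjustment
#' (the Nemenyi form: q = |z| * sqrt(2) referred to the studentized range
#' distribution with infinite df). Stages with fewer than 2 samples are
#' excluded with a warning.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param stages Factor/character vector of stage labels, same length.
#' @return List with `H`, `p_value`, `df`, and `pairwise` (data.frame:
#'   group1, group2, z, p_adjusted).
#' @export
kruskal_wallis_stages <- function(scores, stages) {
  keep <- !is.na(scores) & !is.na(stages)
  scores <- scores[keep]
  stages <- factor(as.character(stages[keep]))
  tab <- table(stages)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("stage(s) with < 2 samples excluded: ",
            paste(small, collapse = ", "))
    keep2 <- !(stages %in% small)
    scores <- scores[keep2]
    stages <- droplevels(stages[keep2])
  }
  if (nlevels(stages) < 2L) stop("need >= 2 stages with >= 2 samples each")
  ht <- stats::kruskal.test(scores, stages)

  ## Dunn z statistics on the pooled ranks with tie correction
  n <- length(scores)
  r <- rank(scores)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_corr
  mean_r <- tapply(r, stages, mean)
  n_g <- tapply(r, stages, length)
  levs <- levels(stages)
  pairs <- utils::combn(levs, 2L)
  k <- nlevels(stages)
  pw <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt(v0 * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_r[[i]] - mean_r[[j]]) / se
    p_adj <- stats::ptukey(abs(z) * sqrt(2), nmeans = k, df = Inf,
                           lower.tail = FALSE)
    c(z = z, p_adjusted = p_adj)
  })
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         z = pw["z", ], p_adjusted = pw["p_adjusted", ],
                         stringsAsFactors = FALSE)
  list(H = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), pairwise = pairwise)
}

#' Multivariate linear association of PD-L1 with infiltration scores
#'
#' Ordinary least squares of PD-L1 expression on the B-cell and CD8 T-cell
#' infiltration scores, with t-based p-values per term.
#'
#' @param pdl1 Per-sample PD-L1 expression.
#' @param bscore,tscore Per-sample infiltration scores.
#' @return data.frame with term, estimate, std_error, t_value, p_value.
#' @export
ols_pdl1_association <- function(pdl1, bscore, tscore) {
  if (length(pdl1) <= 3L) stop("need n > 3 samples")
  if (!all(is.finite(c(pdl1, bscore, tscore)))) stop("non-finite input")
  fit <- stats::lm(pdl1 ~ bscore + tscore)
  if (anyNA(stats::coef(fit)))
    stop("collinear predictors: design matrix is rank-deficient")
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1L],
             std_error = cf[, 2L], t_value = cf[, 3L], p_value = cf[, 4L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratify tumors into PD-L1 / B-cell quadrant groups
#'
#' Samples are split at the median of each variable over all supplied
#' (tumor) samples; "high" means strictly above the median, so for odd n
#' both sides are non-empty. Groups: A = low PD-L1/low B, B = high
#' PD-L1/low B, C = high/high, D = low PD-L1/high B.
#'
#' @param pdl1 Named per-sample PD-L1 values (names = sample IDs).
#' @param bscore Named per-sample B-cell scores over the same samples.
#' @param ties Which side samples exactly at the median fall on:
#'   `"low"` (default; high means strictly above the median) or `"high"`.
#' @return data.frame with sample_id, group, pdl1_value, bscore.
#' @export
stratify_quadrants <- function(pdl1, bscore, ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(pdl1) < 4L) stop("need >= 4 samples to stratify")
  if (!is.null(names(pdl1)) && !is.null(names(bscore))) {
    if (!setequal(names(pdl1), names(bscore)))
      stop("pdl1 and bscore cover different samples")
    bscore <- bscore[names(pdl1)]
  } else if (length(pdl1) != length(bscore)) {
    stop("pdl1 and bscore must have equal length")
  }
  for (v in list(pdl1 = pdl1, bscore = bscore)) {
    if (stats::median(v) == min(v) && stats::median(v) == max(v))
      stop("degenerate stratification: constant variable")
  }
  if (ties == "low") {
    hi_p <- pdl1 > stats::median(pdl1)
    hi_b <- bscore > stats::median(bscore)
  } else {
    hi_p <- pdl1 >= stats::median(pdl1)
    hi_b <- bscore >= stats::median(bscore)
  }
  grp <- ifelse(hi_p, ifelse(hi_b, "C", "B"), ifelse(hi_b, "D", "A"))
  data.frame(sample_id = if (is.null(names(pdl1)))
               as.character(seq_along(pdl1)) else names(pdl1),
             group = unname(grp), pdl1_value = unname(pdl1),
             bscore = unname(bscore), stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit survival curves per group, the log-rank chi-square over
#' pooled event times, and the difference in restricted mean survival
#' (area under each KM curve up to the largest observed time).
#'
#' @param times Follow-up times in days.
#' @param events Logical/0-1 event indicators (TRUE = death observed).
#' @param group_labels Group label per sample.
#' @return List with `curves` (data.frame: group, time, survival, n_risk,
#'   n_event), `logrank_chi2`, `logrank_p`, `df`, `mean_survival`
#'   (restricted mean per group) and `mean_survival_difference_days`
#'   (first minus second group level, two-group case; NA otherwise).
#' @export
km_logrank <- function(times, events, group_labels) {
  events <- as.logical(events)
  grp <- factor(as.character(group_labels))
  if (nlevels(grp) < 2L) stop("need >= 2 groups")
  ev_by_g <- tapply(events, grp, sum)
  if (any(ev_by_g == 0))
    warning("group(s) with zero events: ",
            paste(names(ev_by_g)[ev_by_g == 0], collapse = ", "))
  sf <- survival::survfit(survival::Surv(times, events) ~ grp)
  strata_names <- sub("^grp=", "", rep(names(sf$strata), sf$strata))
  curves <- data.frame(group = strata_names, time = sf$time,
                       survival = sf$surv, n_risk = sf$n.risk,
                       n_event = sf$n.event, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  chi2 <- unname(sd$chisq)
  df <- nlevels(grp) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  rmean <- summary(sf, rmean = max(times))$table[, "rmean"]
  names(rmean) <- sub("^grp=", "", names(rmean))
  diff_days <- if (nlevels(grp) == 2L)
    unname(rmean[levels(grp)[1L]] - rmean[levels(grp)[2L]]) else NA_real_
  list(curves = curves, logrank_chi2 = chi2, logrank_p = p, df = df,
       mean_survival = rmean, mean_survival_difference_days = diff_days)
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling via
#' `survival::coxph`. Multivariate mode fits all covariates jointly;
#' univariate mode fits each covariate alone. Categorical covariates are
#' expanded against a stated reference level (stage I, sex male, mutation
#' status non-mutation, score dichotomies low).
#'
#' @param times Follow-up times in days.
#' @param events Logical event indicators.
#' @param covariates data.frame of per-sample covariates (numeric or
#'   factor/character).
#' @param mode "multivariate" (default) or "univariate".
#' @return data.frame with model, covariate, level, coef, hazard_ratio,
#'   se, z, p_value, n, n_events.
#' @export
cox_regression <- function(times, events, covariates,
                           mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  reference_levels <- c(stage = "I", sex = "male",
                        egfr_status = "non-mutation",
                        kras_status = "non-mutation")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- factor(as.character(v))
      ref <- reference_levels[nm]
      if (!is.na(ref) && ref %in% levels(v)) v <- stats::relevel(v, ref)
      if ("low" %in% levels(v)) v <- stats::relevel(v, "low")
      covariates[[nm]] <- v
    }
  }
  fit_one <- function(df, label) {
    n_coef <- sum(vapply(df, function(v)
      if (is.factor(v)) nlevels(v) - 1L else 1L, integer(1L)))
    keep <- stats::complete.cases(df) & !is.na(times) & !is.na(events)
    df <- df[keep, , drop = FALSE]
    tt <- times[keep]; ee <- as.logical(events[keep])
    if (sum(ee) < 5L * n_coef)
      warning(sprintf("model '%s': fewer than 5 events per coefficient",
                      label))
    fml <- stats::as.formula(paste(
      "survival::Surv(tt, ee) ~", paste(names(df), collapse = " + ")))
    fit <- tryCatch(
      survival::coxph(fml, data = df, ties = "breslow",
                      control = survival::coxph.control(iter.max = 100L,
                                                        eps = 1e-9)),
      error = function(e) stop("Cox fit failed for '", label, "': ",
                               conditionMessage(e)))
    cf <- stats::coef(fit)
    if (anyNA(cf))
      stop("rank-deficient design: covariate(s) ",
           paste(names(cf)[is.na(cf)], collapse = ", "),
           " are collinear")
    if (any(abs(cf) > 15))
      stop("complete separation suspected: |coefficient| > 15 for ",
           names(cf)[which.max(abs(cf))])
    sm <- summary(fit)$coefficients
    data.frame(model = label, covariate = sub("[^ ]*$", "",
                                              rownames(sm), perl = TRUE),
               term = rownames(sm), coef = sm[, "coef"],
               hazard_ratio = sm[, "exp(coef)"], se = sm[, "se(coef)"],
               z = sm[, "z"], p_value = sm[, "Pr(>|z|)"],
               n = fit$n, n_events = fit$nevent,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (mode == "multivariate") {
    out <- fit_one(covariates, "multivariate")
  } else {
    out <- do.call(rbind, lapply(names(covariates), function(nm)
      fit_one(covariates[, nm, drop = FALSE], nm)))
    out$model <- "univariate"
  }
  out$covariate <- NULL
  out
}
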