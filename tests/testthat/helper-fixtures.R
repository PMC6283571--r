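# Shared fixtures, built once per test run.

# small deterministic expression matrix with named genes/samples
toy_matrix <- function(n_genes = 20, n_samples = 6, seed = 101) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, mean = 5), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  m
}

# the default synthetic cohort, generated once and cached
.fixture_env <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_cohort(cohort_params(seed = 42))
  .fixture_env$cohort
}

tumor_ids_of <- function(sim) {
  sim$clinical$sample_id[sim$clinical$tissue == "tumor"]
}

# independent brute-force ssGSEA oracle: literal evaluation of the
# summed-difference definition for a single sample, no shared code with
# the package implementation
ssgsea_brute <- function(x, set_genes, alpha) {
  n <- length(x)
  ord <- names(sort(x, decreasing = TRUE))
  # average descending ranks for ties
  r_desc <- rank(-x)[ord]
  hit <- ord %in% set_genes
  w <- (n - r_desc + 1)^alpha
  num <- 0; p_in <- 0; p_out <- 0; total <- sum(w[hit])
  run <- numeric(n)
  for (i in seq_len(n)) {
    if (hit[i]) p_in <- p_in + w[i] / total
    else p_out <- p_out + 1 / (n - sum(hit))
    run[i] <- p_in - p_out
  }
  sum(run)
}

# independent brute-force enrichment-score oracle: returns the whole
# running sum, accumulated step by step
es_brute_running <- function(metric, hit, weight) {
  n <- length(metric)
  nh <- sum(hit)
  nr <- sum(abs(metric[hit])^weight)
  run <- numeric(n); acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) abs(metric[i])^weight / nr else -1 / (n - nh)
    run[i] <- acc
  }
  run
}

es_brute <- function(metric, hit, weight) {
  run <- es_brute_running(metric, hit, weight)
  run[which.max(abs(run))]
}
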