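# Shared fixtures and independent oracles.

# Small synthetic experiment for unit tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(sim_config(n_genes = 400, seed = 101L))
    }
    cache
  }
})

# Build an expr_matrix directly from a matrix of proportions (columns need
# not sum to 1; used to plant exact values for arithmetic identities).
expr_from_E <- function(E, epsilon = 1e-12) {
  structure(
    list(E = E, log2E = log2(E + epsilon), epsilon = epsilon,
         gene_ids = rownames(E), sample_ids = colnames(E)),
    class = "expr_matrix"
  )
}

# Minimal design covering arbitrary sample columns, one block.
tiny_design <- function(sample_ids, block = 1L) {
  data.frame(
    sample_id = sample_ids,
    population_id = sub("_(cadmium|salt)$", "", sample_ids),
    regime = "Cad",
    replicate = 1L,
    diet = ifelse(grepl("cadmium$", sample_ids), "cadmium", "salt"),
    block = block,
    stringsAsFactors = FALSE
  )
}

# Independent step-up oracle for Benjamini-Hochberg q-values.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Brute-force CMH statistic from the defining formula, one table at a time.
cmh_formula_oracle <- function(tables, correct = TRUE) {
  K <- dim(tables)[3]
  sum_dev <- 0
  sum_V <- 0
  for (k in seq_len(K)) {
    t2 <- tables[, , k]
    n <- sum(t2)
    if (n <= 1) next
    E <- sum(t2[1, ]) * sum(t2[, 1]) / n
    V <- sum(t2[1, ]) * sum(t2[2, ]) * sum(t2[, 1]) * sum(t2[, 2]) / (n^2 * (n - 1))
    sum_dev <- sum_dev + (t2[1, 1] - E)
    sum_V <- sum_V + V
  }
  dev <- abs(sum_dev)
  if (correct) dev <- max(dev - 0.5, 0)
  stat <- dev^2 / sum_V
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Random stratified 2x2 tables with positive cells (for oracle comparisons).
random_strat_tables <- function(K = 5) {
  array(rpois(4 * K, lambda = 8) + 1L, dim = c(2, 2, K))
}
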