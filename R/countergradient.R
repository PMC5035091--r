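#' Screen for ancestrally plastic genes
#'
#' Genes whose expression in the naive grand ancestor (GA) responds to diet:
#' `|log2FC| > threshold` between the cadmium and salt assays.  The polarity
#' Z records the direction of the ancestral plastic response (+1 =
#' up-regulated in cadmium) and is later used to polarize evolved
#' divergence.  Genes with an exactly zero fold change (possible only on
#' degenerate input) are excluded rather than given an arbitrary polarity.
#'
#' @param expr an [normalize_expression()] object containing both GA samples.
#' @param design design table.
#' @param threshold strict |log2FC| cutoff (default 0.4).
#' @param population ancestor population id (default `"GA"`).
#' @return A gene screen set: `data.frame` with `gene_id` and `polarity`,
#'   with attributes `name` and `thresholds`.
#' @export
screen_ga_plastic <- function(expr, design, threshold = 0.4, population = "GA") {
  lfc <- diet_log2fc(expr, design, population)
  keep <- abs(lfc) > threshold & lfc != 0
  structure(
    data.frame(gene_id = names(lfc)[keep],
               polarity = as.integer(sign(lfc[keep])),
               log2fc = unname(lfc[keep]),
               stringsAsFactors = FALSE, row.names = NULL),
    name = "ancestral_plastic",
    thresholds = c(log2fc = threshold)
  )
}

#' Screen for genes with an evolved selection-history effect
#'
#' Genes whose average expression (across diets) differs between two evolved
#' regimes at FDR `q_history < q_threshold` in the two-regime model fit.
#' Polarity is the sign of the history effect (first regime minus second).
#'
#' @param de result of [fit_gene_models()] with the
#'   `two_regimes_both_diets` contrast.
#' @param q_threshold strict q-value cutoff (default 0.1).
#' @return A gene screen set (see [screen_ga_plastic()]).
#' @export
screen_history_genes <- function(de, q_threshold = 0.1) {
  keep <- !is.na(de$q_history) & de$q_history < q_threshold &
    de$estimate_history != 0
  structure(
    data.frame(gene_id = de$gene_id[keep],
               polarity = as.integer(sign(de$estimate_history[keep])),
               stringsAsFactors = FALSE, row.names = NULL),
    name = "history_significant",
    thresholds = c(q = q_threshold)
  )
}

#' Intersect two gene screen sets
#'
#' Intersection by `gene_id`; polarity is taken from the first set (for the
#' countergradient analysis, the ancestral-plasticity polarity Z).  The
#' order of the two screens is immaterial to membership.
#'
#' @param set_a,set_b gene screen sets.
#' @return A gene screen set restricted to the common genes, with `set_a`'s
#'   polarity.
#' @export
intersect_screens <- function(set_a, set_b) {
  keep <- set_a$gene_id %in% set_b$gene_id
  structure(
    set_a[keep, , drop = FALSE],
    name = paste(attr(set_a, "name"), attr(set_b, "name"), sep = "&"),
    thresholds = c(attr(set_a, "thresholds"), attr(set_b, "thresholds"))
  )
}

#' Polarized per-block expression divergence between population pairs
#'
#' For gene i and block j, with the block's Cad-regime population `Cad_j`
#' and Salt-regime population `Salt_j`, computes
#' `0.5 * Z_i * (log2 E(cadmium, i, Cad_j) + log2 E(salt, i, Cad_j)
#'             - log2 E(cadmium, i, Salt_j) - log2 E(salt, i, Salt_j))`
#' i.e. the evolved Cad-vs-Salt difference averaged over assay diets and
#' polarized by the direction Z of ancestral plasticity.  Negative per-block
#' means indicate countergradient evolution (evolved divergence opposing
#' ancestral plasticity).
#'
#' @param expr an [normalize_expression()] object (logs are
#'   epsilon-stabilized).
#' @param design design table.
#' @param gene_set gene screen set supplying membership and Z.
#' @param regimes the two constant regimes, first polarized against second.
#' @return List with `per_gene` (gene x block matrix) and `block_means`
#'   (named numeric, mean over member genes per block).
#' @export
polarized_pair_divergence <- function(expr, design, gene_set,
                                      regimes = c("Cad", "Salt")) {
  missing_genes <- setdiff(gene_set$gene_id, expr$gene_ids)
  if (length(missing_genes)) {
    stop(sprintf("gene(s) in set absent from expression matrix: %s",
                 paste(utils::head(missing_genes, 5), collapse = ", ")))
  }
  d <- design[design$regime %in% regimes, ]
  blocks <- sort(unique(d$block))
  z <- gene_set$polarity
  per_gene <- matrix(NA_real_, nrow = nrow(gene_set), ncol = length(blocks),
                     dimnames = list(gene_set$gene_id, paste0("block", blocks)))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    pop1 <- unique(d$population_id[d$block == b & d$regime == regimes[1]])
    pop2 <- unique(d$population_id[d$block == b & d$regime == regimes[2]])
    if (length(pop1) != 1L || length(pop2) != 1L) {
      stop(sprintf("block %d must contain exactly one %s and one %s population",
                   b, regimes[1], regimes[2]))
    }
    l <- expr$log2E[gene_set$gene_id, , drop = FALSE]
    per_gene[, bi] <- 0.5 * z * (
      l[, sample_of(design, pop1, "cadmium")] + l[, sample_of(design, pop1, "salt")] -
      l[, sample_of(design, pop2, "cadmium")] - l[, sample_of(design, pop2, "salt")]
    )
  }
  list(per_gene = per_gene, block_means = colMeans(per_gene))
}

#' Sign test for the opposing fraction
#'
#' One-degree-of-freedom goodness-of-fit chi-square (no continuity
#' correction) of the number of genes whose evolved divergence opposes
#' ancestral plasticity against the null expectation of half.
#'
#' @param n_opposing number of opposing genes.
#' @param n_total total genes tested.
#' @return List with `chi2`, `df`, `p`.
#' @export
opposing_fraction_test <- function(n_opposing, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  stopifnot(n_opposing >= 0, n_opposing <= n_total)
  ht <- stats::chisq.test(c(n_opposing, n_total - n_opposing),
                          p = c(0.5, 0.5), correct = FALSE)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-sample t-test of per-block mean divergence
#'
#' Uses the replicate population pairs (blocks), not genes, as the unit of
#' replication: two-sided one-sample t-test of the per-block polarized
#' divergence means against zero.
#'
#' @param per_block_means numeric vector of per-block means (>= 2 values).
#' @return List with `t`, `df`, `p`, `mean`.
#' @export
pair_mean_test <- function(per_block_means) {
  if (length(per_block_means) < 2L) stop("need at least two block means")
  if (stats::sd(per_block_means) == 0) {
    stop("zero standard deviation among block means; t undefined")
  }
  ht <- stats::t.test(per_block_means, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean = unname(ht$estimate))
}

#' Countergradient analysis
#'
#' Convenience wrapper combining the two screens, their intersection, the
#' polarized per-block divergence and its two significance tests.
#'
#' @param expr an [normalize_expression()] object.
#' @param design design table.
#' @param de two-regime model fit (see [screen_history_genes()]).
#' @param ga_threshold ancestral-plasticity |log2FC| cutoff.
#' @param q_threshold history-effect q cutoff.
#' @return List with `overlap` (screen set), `divergence`
#'   ([polarized_pair_divergence()] output), `n_opposing`, `n_total`,
#'   `sign_test`, `block_test`.
#' @export
countergradient_analysis <- function(expr, design, de,
                                     ga_threshold = 0.4, q_threshold = 0.1) {
  ga_set <- screen_ga_plastic(expr, design, threshold = ga_threshold)
  hist_set <- screen_history_genes(de, q_threshold = q_threshold)
  overlap <- intersect_screens(ga_set, hist_set)
  if (nrow(overlap) == 0L) stop("no genes pass both screens")
  div <- polarized_pair_divergence(expr, design, overlap)
  ## a gene opposes ancestral plasticity if its polarized evolved divergence
  ## (averaged over blocks) is negative
  gene_means <- rowMeans(div$per_gene)
  n_opp <- sum(gene_means < 0)
  list(
    overlap = overlap,
    divergence = div,
    n_opposing = n_opp,
    n_total = length(gene_means),
    sign_test = opposing_fraction_test(n_opp, length(gene_means)),
    block_test = pair_mean_test(div$block_means)
  )
}
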