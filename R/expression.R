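## Multivariate hypergeometric draw: sample `target` items without
## replacement from categories with sizes `x` (sequential conditional
## hypergeometric; exact).
rmvhyper <- function(x, target) {
  stopifnot(target <= sum(x))
  out <- integer(length(x))
  remaining <- sum(x)
  left <- target
  for (i in seq_along(x)) {
    if (left == 0L) break
    remaining <- remaining - x[i]
    out[i] <- stats::rhyper(1L, x[i], remaining, left)
    left <- left - out[i]
  }
  out
}

#' Down-sample counts to equal coverage within blocks
#'
#' Differences in sequencing depth among samples translate into unequal
#' statistical power, so within every block each sample's reads are
#' down-sampled without replacement (multivariate hypergeometric over the
#' sample's gene counts) to the minimum pre-existing column total of that
#' block.  Samples already at the minimum are returned unchanged.
#'
#' @param counts integer gene x sample matrix.
#' @param design design table covering every column of `counts`.
#' @param seed integer seed; the operation is deterministic given the seed.
#' @return Count matrix of the same shape whose column totals are constant
#'   within each block.
#' @export
downsample_counts <- function(counts, design, seed = 1L) {
  validate_counts(counts, design)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop(sprintf("sample with zero total count: %s",
                 colnames(counts)[which(totals == 0)[1]]))
  }
  set.seed(seed)
  out <- counts
  design <- design[match(colnames(counts), design$sample_id), ]
  for (b in sort(unique(design$block))) {
    cols <- which(design$block == b)
    if (length(cols) < 2L) next
    target <- min(totals[cols])
    for (j in cols) {
      if (totals[j] > target) {
        out[, j] <- rmvhyper(counts[, j], target)
      }
    }
  }
  out
}

#' Normalize counts to per-sample expression proportions
#'
#' Expression of gene i in sample s is the proportion
#' `E = count / sample total` (proportional to the concentration of the
#' gene's cDNA in the sample), together with its stabilized log2 transform
#' `log2(E + epsilon)`.
#'
#' @param counts integer gene x sample matrix with positive column totals.
#' @param epsilon pseudo-proportion added before taking logs.  Default
#'   `1 / (2 * max(colSums(counts)))`: half the smallest representable
#'   proportion, so zero-count genes stay finite without dominating ranks.
#' @return An object of class `expr_matrix`: list with `E`, `log2E`
#'   (matrices), `epsilon`, `gene_ids`, `sample_ids`.
#' @export
normalize_expression <- function(counts, epsilon = NULL) {
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop(sprintf("sample with zero total count: %s",
                 colnames(counts)[which(totals <= 0)[1]]))
  }
  if (is.null(epsilon)) epsilon <- 1 / (2 * max(totals))
  stopifnot(epsilon > 0)
  E <- sweep(counts, 2, totals, "/")
  structure(
    list(E = E, log2E = log2(E + epsilon), epsilon = epsilon,
         gene_ids = rownames(counts), sample_ids = colnames(counts)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (epsilon = %.3g)\n",
              length(x$gene_ids), length(x$sample_ids), x$epsilon))
  invisible(x)
}

#' Per-gene diet log2 fold change for one population
#'
#' `log2E(cadmium) - log2E(salt)` for the population's two samples; positive
#' values mean higher expression in the cadmium diet.
#'
#' @param expr an [normalize_expression()] object.
#' @param design design table.
#' @param population_id population assayed in both diets.
#' @return Named numeric vector, one value per gene.
#' @export
diet_log2fc <- function(expr, design, population_id) {
  s_cad <- sample_of(design, population_id, "cadmium")
  s_salt <- sample_of(design, population_id, "salt")
  if (!all(c(s_cad, s_salt) %in% expr$sample_ids)) {
    stop(sprintf("samples of population %s absent from expression matrix", population_id))
  }
  expr$log2E[, s_cad] - expr$log2E[, s_salt]
}

## RSS of every gene's OLS fit for a given design matrix (genes x samples Y).
rss_all_genes <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    stop(sprintf("rank-deficient design; aliased column(s): %s",
                 paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", ")))
  }
  res <- qr.resid(qx, t(Y))
  colSums(res^2)
}

#' Fit per-gene fixed-effect expression models
#'
#' Ordinary least-squares fits of `log2E` on the design of the requested
#' contrast, gene by gene (all genes share one design matrix):
#'
#' * `two_regimes_both_diets`: `~ diet + history + diet:history + block`,
#'   comparing two regimes using both diet assays (20 samples).
#' * `two_regimes_one_diet`: `~ history + block` within a single diet.
#' * `one_regime_diet_effect`: `~ diet + block` within a single regime.
#'
#' Factors use sum-to-zero contrasts and each effect's p-value is the
#' partial F-test dropping that effect's columns from the full model (for
#' the balanced layouts this equals the sequential test).  Benjamini-
#' Hochberg q-values are computed per effect across tested genes.  Genes
#' whose total count is below `min_total` are reported untested (`NA`
#' statistics) because OLS on logs of near-zero proportions is unstable.
#'
#' @param expr an [normalize_expression()] object.
#' @param design design table.
#' @param contrast one of the three model layouts above.
#' @param regimes two regimes (for the two-regime contrasts); `log2FC_history`
#'   and the history polarity are `regimes[1]` minus `regimes[2]`.
#' @param regime single regime for `one_regime_diet_effect`.
#' @param diet single diet for `two_regimes_one_diet`.
#' @param counts optional count matrix used for the `min_total` filter; if
#'   `NULL` all genes are tested.
#' @param min_total minimum summed count for a gene to be tested.
#' @return `data.frame` (one row per gene) with `tested`, `log2FC_diet`,
#'   `log2FC_history`, and per-effect estimate/p/q columns as applicable.
#' @export
fit_gene_models <- function(expr, design,
                            contrast = c("two_regimes_both_diets",
                                         "two_regimes_one_diet",
                                         "one_regime_diet_effect"),
                            regimes = c("Cad", "Salt"),
                            regime = NULL, diet = NULL,
                            counts = NULL, min_total = 10L) {
  contrast <- match.arg(contrast)
  d <- switch(contrast,
    two_regimes_both_diets = design[design$regime %in% regimes, ],
    two_regimes_one_diet = {
      stopifnot(!is.null(diet))
      design[design$regime %in% regimes & design$diet == diet, ]
    },
    one_regime_diet_effect = {
      stopifnot(!is.null(regime))
      design[design$regime == regime, ]
    }
  )
  d <- d[d$sample_id %in% expr$sample_ids, ]
  if (contrast != "one_regime_diet_effect") {
    n_rep <- table(unique(d[, c("population_id", "regime")])$regime)
    if (!all(n_rep == 5L)) stop("contrast requires 5 replicate populations per regime")
  }

  d$diet_f <- factor(d$diet, levels = DIETS)
  d$hist_f <- factor(d$regime, levels = intersect(c(regimes, REGIMES_ALL), unique(d$regime)))
  d$block_f <- factor(d$block)

  terms_used <- switch(contrast,
    two_regimes_both_diets = c("diet", "history", "diet:history", "block"),
    two_regimes_one_diet = c("history", "block"),
    one_regime_diet_effect = c("diet", "block")
  )
  fml <- switch(contrast,
    two_regimes_both_diets = ~ diet_f * hist_f + block_f,
    two_regimes_one_diet = ~ hist_f + block_f,
    one_regime_diet_effect = ~ diet_f + block_f
  )
  X <- stats::model.matrix(fml, d, contrasts.arg = lapply(
    stats::setNames(nm = intersect(c("diet_f", "hist_f", "block_f"), all.vars(fml))),
    function(nm) "contr.sum"
  ))
  assign_map <- attr(X, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")
  col_term <- c("(Intercept)", term_labels)[assign_map + 1L]
  label_of <- c(diet = "diet_f", history = "hist_f", block = "block_f",
                "diet:history" = "diet_f:hist_f")

  Y <- expr$log2E[, d$sample_id, drop = FALSE]
  n_genes <- nrow(Y)
  tested <- rep(TRUE, n_genes)
  if (!is.null(counts)) {
    tested <- rowSums(counts[, d$sample_id, drop = FALSE]) >= min_total
  }

  rss_full <- rss_all_genes(Y, X)
  df_res <- nrow(X) - ncol(X)
  out <- data.frame(gene_id = expr$gene_ids, tested = tested,
                    stringsAsFactors = FALSE)

  ## descriptive fold changes
  if ("diet" %in% terms_used) {
    cad <- d$sample_id[d$diet == "cadmium"]
    salt <- d$sample_id[d$diet == "salt"]
    out$log2FC_diet <- rowMeans(expr$log2E[, cad, drop = FALSE]) -
      rowMeans(expr$log2E[, salt, drop = FALSE])
  }
  if ("history" %in% terms_used) {
    g1 <- d$sample_id[d$regime == regimes[1]]
    g2 <- d$sample_id[d$regime == regimes[2]]
    out$log2FC_history <- rowMeans(expr$log2E[, g1, drop = FALSE]) -
      rowMeans(expr$log2E[, g2, drop = FALSE])
  }

  degenerate <- rss_full < 1e-18 & apply(Y, 1, stats::var) < 1e-18
  for (tm in terms_used) {
    drop_cols <- col_term == label_of[[tm]]
    df_t <- sum(drop_cols)
    rss_red <- rss_all_genes(Y, X[, !drop_cols, drop = FALSE])
    Fstat <- ((rss_red - rss_full) / df_t) / (rss_full / df_res)
    p <- stats::pf(Fstat, df_t, df_res, lower.tail = FALSE)
    est <- switch(tm,
      diet = out$log2FC_diet,
      history = out$log2FC_history,
      rep(NA_real_, n_genes)
    )
    p[degenerate] <- 1
    if (!is.null(est)) est[degenerate] <- 0
    p[!tested] <- NA_real_
    key <- gsub(":", "_x_", tm)
    out[[paste0("estimate_", key)]] <- est
    out[[paste0("p_", key)]] <- p
    q <- rep(NA_real_, n_genes)
    q[tested] <- bh_adjust(p[tested])$q
    out[[paste0("q_", key)]] <- q
  }
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return `data.frame` with columns `p` and `q` in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals))) stop("NA/NaN p-value")
  if (any(pvals < 0 | pvals > 1)) stop("p-value outside [0, 1]")
  data.frame(p = pvals, q = stats::p.adjust(pvals, method = "BH"))
}
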