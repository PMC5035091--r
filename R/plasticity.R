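#' Ancestor reference states
#'
#' The four reference expression states used by the plasticity screens and
#' the adaptive-distance metric, taken from the two diet-adapted ancestors:
#' `O_cad` (AC in cadmium) and `O_salt` (AS in salt) are the "Optimal"
#' states, `N_cad` (AS in cadmium) and `N_salt` (AC in salt) the
#' "Non-adapted" states.  Values are normalized expression proportions E;
#' the matching epsilon-stabilized log2 values are included for fold-change
#' screens.
#'
#' @param expr an [normalize_expression()] object containing all four AC/AS
#'   samples.
#' @param design design table.
#' @return `data.frame` per gene with E-scale columns `O_cad`, `O_salt`,
#'   `N_cad`, `N_salt` and log2-scale columns `lO_cad`, `lO_salt`, `lN_cad`,
#'   `lN_salt`.
#' @export
ancestor_states <- function(expr, design) {
  s <- c(O_cad = sample_of(design, "AC", "cadmium"),
         O_salt = sample_of(design, "AS", "salt"),
         N_cad = sample_of(design, "AS", "cadmium"),
         N_salt = sample_of(design, "AC", "salt"))
  if (!all(s %in% expr$sample_ids)) stop("missing ancestor sample(s)")
  out <- data.frame(gene_id = expr$gene_ids, stringsAsFactors = FALSE)
  for (nm in names(s)) {
    out[[nm]] <- expr$E[, s[[nm]]]
    out[[paste0("l", nm)]] <- expr$log2E[, s[[nm]]]
  }
  out
}

#' Screen for predicted targets of increased plasticity
#'
#' Genes for which selection in a heterogeneous environment is predicted to
#' build plasticity: (i) the two "Optimal" states differ substantially,
#' `|log2(O_cad / O_salt)| > opt_diff_thr`; and (ii) both ancestors are only
#' weakly plastic relative to a reference divergence D:
#' `|log2FC(diet)| < ratio * D` for each of AC and AS.  By default D is the
#' optimal-pair difference `|log2(O_cad / O_salt)|` (the same quantity as
#' criterion i); `reference = "within_diet"` instead requires the ancestor
#' plasticities to be below `ratio * min_d |log2(AC_d / AS_d)|`, the
#' AC-vs-AS difference within each assay diet.  The polarity
#' `Y = sign(log2(O_cad / O_salt))` makes plasticity toward each diet's
#' optimum positive.
#'
#' @param expr an [normalize_expression()] object.
#' @param design design table.
#' @param opt_diff_thr strict threshold on the optimal-pair |log2FC|.
#' @param ratio multiple of the reference divergence the ancestor
#'   plasticities must stay strictly below.
#' @param reference reference divergence for criterion (ii).
#' @return A gene screen set with polarity Y.
#' @export
screen_increased <- function(expr, design, opt_diff_thr = 0.4, ratio = 0.5,
                             reference = c("optimal_pair", "within_diet")) {
  reference <- match.arg(reference)
  anc <- ancestor_states(expr, design)
  d_opt <- anc$lO_cad - anc$lO_salt
  plast_ac <- diet_log2fc(expr, design, "AC")
  plast_as <- diet_log2fc(expr, design, "AS")
  D <- if (reference == "optimal_pair") {
    abs(d_opt)
  } else {
    pmin(abs(anc$lO_cad - anc$lN_cad), abs(anc$lN_salt - anc$lO_salt))
  }
  keep <- abs(d_opt) > opt_diff_thr &
    abs(plast_ac) < ratio * D & abs(plast_as) < ratio * D & d_opt != 0
  structure(
    data.frame(gene_id = anc$gene_id[keep],
               polarity = as.integer(sign(d_opt[keep])),
               stringsAsFactors = FALSE, row.names = NULL),
    name = "increased_plasticity_targets",
    thresholds = c(opt_diff = opt_diff_thr, ratio = ratio),
    reference = reference
  )
}

#' Screen for predicted targets of reduced plasticity
#'
#' Genes for which the optimal expression is similar in both diets but the
#' ancestors are strongly (and consistently) perturbed away from it in
#' their foreign diet: (i) `|log2(O_d / N_d)| > on_diff_thr` in both diets
#' with the same sign (the Optimal state higher in both or lower in both);
#' and (ii) the optima are close relative to that perturbation,
#' `|log2(O_cad / O_salt)| < ratio * min_d |log2(O_d / N_d)|`.  The score
#' for this set is absolute plasticity, so no polarity is needed
#' (polarity is set to +1).
#'
#' @inheritParams screen_increased
#' @param on_diff_thr strict threshold on the Optimal-vs-Non-adapted
#'   |log2FC| in each diet.
#' @return A gene screen set.
#' @export
screen_decreased <- function(expr, design, on_diff_thr = 0.3, ratio = 0.5) {
  anc <- ancestor_states(expr, design)
  d_on_cad <- anc$lO_cad - anc$lN_cad
  d_on_salt <- anc$lO_salt - anc$lN_salt
  d_opt <- anc$lO_cad - anc$lO_salt
  keep <- abs(d_on_cad) > on_diff_thr & abs(d_on_salt) > on_diff_thr &
    sign(d_on_cad) == sign(d_on_salt) &
    abs(d_opt) < ratio * pmin(abs(d_on_cad), abs(d_on_salt))
  structure(
    data.frame(gene_id = anc$gene_id[keep],
               polarity = rep(1L, sum(keep)),
               stringsAsFactors = FALSE, row.names = NULL),
    name = "decreased_plasticity_targets",
    thresholds = c(on_diff = on_diff_thr, ratio = ratio)
  )
}

population_score <- function(expr, design, set, fun, populations = NULL) {
  if (nrow(set) == 0L) stop("empty gene set")
  if (is.null(populations)) populations <- populations_of(design, REGIMES_EVOLVED)
  rows <- lapply(populations, function(pop) {
    lfc <- diet_log2fc(expr, design, pop)[set$gene_id]
    drow <- design[design$population_id == pop, ][1, ]
    data.frame(population_id = pop, regime = drow$regime,
               replicate = drow$replicate, block = drow$block,
               score = mean(fun(lfc, set$polarity)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-population polarized (adaptive) plasticity score
#'
#' For each population, the mean over set genes of `Y * log2FC(diet)`:
#' plasticity in the direction of the between-diet difference in optimal
#' expression counts as positive.
#'
#' @param expr an [normalize_expression()] object.
#' @param design design table.
#' @param set gene screen set supplying membership and polarity Y.
#' @param populations populations to score (default: all evolved
#'   populations).
#' @return `data.frame` with `population_id`, `regime`, `replicate`,
#'   `block`, `score`.
#' @export
polarized_plasticity_score <- function(expr, design, set, populations = NULL) {
  population_score(expr, design, set, function(lfc, pol) pol * lfc, populations)
}

#' Per-population absolute plasticity score
#'
#' Mean over set genes of `|log2FC(diet)|`; invariant to polarity and to
#' exchanging the diet labels.
#'
#' @inheritParams polarized_plasticity_score
#' @return As [polarized_plasticity_score()].
#' @export
absolute_plasticity_score <- function(expr, design, set, populations = NULL) {
  population_score(expr, design, set, function(lfc, pol) abs(lfc), populations)
}

#' Adaptive distance Phi
#'
#' The scaled distance of a population's expression from the optimal state,
#' per diet and gene: `Phi = (E - O) / (N - O)`, where O is the diet-adapted
#' ancestor's expression in that diet and N the non-adapted ancestor's.
#' Phi = 0 means expression at the optimum, Phi = 1 as poor as the
#' non-adapted ancestor; values outside [0, 1] (overshooting, or worse than
#' the non-adapted state) are reported raw and flagged, not clamped.  Genes
#' with `N == O` have undefined Phi and are dropped with a warning.  Phi is
#' invariant to any affine rescaling applied to E, O and N jointly, so the
#' choice of expression scale does not matter beyond monotonicity.
#'
#' @param expr an [normalize_expression()] object (E-scale proportions are
#'   used).
#' @param design design table.
#' @param set gene screen set defining the genes of interest.
#' @param populations populations to evaluate (default: all evolved
#'   populations).
#' @return List with `per_gene` (long `data.frame`: `diet`, `gene_id`,
#'   `population_id`, `phi`, `out_of_range`) and `phi_bar` (`data.frame` of
#'   per-population per-diet means over set genes).
#' @export
adaptive_distance <- function(expr, design, set, populations = NULL) {
  if (nrow(set) == 0L) stop("empty gene set")
  if (is.null(populations)) populations <- populations_of(design, REGIMES_EVOLVED)
  anc <- ancestor_states(expr, design)
  anc <- anc[match(set$gene_id, anc$gene_id), ]
  refs <- list(cadmium = list(O = anc$O_cad, N = anc$N_cad),
               salt = list(O = anc$O_salt, N = anc$N_salt))
  rows <- list()
  for (dd in DIETS) {
    O <- refs[[dd]]$O
    N <- refs[[dd]]$N
    ok <- N != O
    if (any(!ok)) {
      warning(sprintf("dropping %d gene(s) with N == O in diet %s", sum(!ok), dd))
    }
    for (pop in populations) {
      E <- expr$E[set$gene_id, sample_of(design, pop, dd)]
      phi <- (E[ok] - O[ok]) / (N[ok] - O[ok])
      rows[[paste(dd, pop)]] <- data.frame(
        diet = dd, gene_id = set$gene_id[ok], population_id = pop,
        phi = phi, out_of_range = phi < 0 | phi > 1,
        stringsAsFactors = FALSE
      )
    }
  }
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  phi_bar <- stats::aggregate(phi ~ diet + population_id, data = per_gene, FUN = mean)
  idx <- match(phi_bar$population_id, design$population_id)
  phi_bar$regime <- design$regime[idx]
  phi_bar$replicate <- design$replicate[idx]
  phi_bar$block <- design$block[idx]
  names(phi_bar)[names(phi_bar) == "phi"] <- "phi_bar"
  list(per_gene = per_gene, phi_bar = phi_bar)
}

#' One-way ANOVA and Tukey HSD across regimes
#'
#' Compares a per-population score (polarized or absolute plasticity, or
#' mean adaptive distance) among the four selective regimes: one-way ANOVA
#' F-test, the fraction of total variance attributable to between-regime
#' differences (`SS_regime / SS_total`), and Tukey HSD adjusted p-values
#' (studentized-range distribution) for all six regime pairs.
#'
#' @param scores `data.frame` with columns `regime` and `score`
#'   (one row per population; balanced groups required).
#' @return List with `F`, `df`, `p`, `var_fraction`, `regime_means`,
#'   `tukey` (`data.frame`: `pair`, `diff`, `p_adj`).
#' @export
regime_anova_tukey <- function(scores) {
  if (length(unique(table(scores$regime))) != 1L) {
    stop("unbalanced regime groups")
  }
  scores$regime <- factor(scores$regime)
  if (stats::var(scores$score) == 0) {
    pairs <- utils::combn(levels(scores$regime), 2)
    return(list(F = NA_real_, df = c(nlevels(scores$regime) - 1L,
                                     nrow(scores) - nlevels(scores$regime)),
                p = 1, var_fraction = 0,
                regime_means = tapply(scores$score, scores$regime, mean),
                tukey = data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                                   diff = 0, p_adj = 1)))
  }
  fit <- stats::aov(score ~ regime, data = scores)
  an <- summary(fit)[[1]]
  ss <- an[["Sum Sq"]]
  tk <- stats::TukeyHSD(fit)$regime
  list(
    F = an[["F value"]][1],
    df = an[["Df"]],
    p = an[["Pr(>F)"]][1],
    var_fraction = ss[1] / sum(ss),
    regime_means = tapply(scores$score, scores$regime, mean),
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL)
  )
}

#' Heterogeneity-class likelihood-ratio test
#'
#' Tests whether populations from heterogeneous regimes (Temp, Spatial)
#' differ from constant-regime populations (Cad, Salt) in a per-population
#' score, over and above the selective history nested within each class and
#' the block structure.  The full linear model has an explicit
#' heterogeneity-class column, a within-class history column (second regime
#' of each class vs the first) and block (fixed effect); the reduced model
#' removes only the class column.  The comparison is a likelihood-ratio
#' chi-square with df equal to the number of dropped parameters (here 1).
#'
#' @param scores `data.frame` with columns `regime`, `block`, `score`.
#' @return List with `chi2`, `df`, `p`.
#' @export
heterogeneity_test <- function(scores) {
  stopifnot(all(scores$regime %in% REGIMES_EVOLVED))
  het <- as.numeric(scores$regime %in% c("Temp", "Spatial"))
  hist_within <- as.numeric(scores$regime %in% c("Salt", "Spatial"))
  block <- factor(scores$block)
  X_red <- stats::model.matrix(~ hist_within + block)
  X_full <- cbind(X_red, het = het)
  if (qr(X_full)$rank < ncol(X_full)) stop("singular model (aliased terms)")
  fit_full <- stats::lm.fit(X_full, scores$score)
  fit_red <- stats::lm.fit(X_red, scores$score)
  n <- nrow(scores)
  rss_full <- sum(fit_full$residuals^2)
  rss_red <- sum(fit_red$residuals^2)
  if (rss_full <= 0) stop("saturated fit; likelihood ratio undefined")
  chi2 <- n * (log(rss_red) - log(rss_full))
  df <- ncol(X_full) - ncol(X_red)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
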