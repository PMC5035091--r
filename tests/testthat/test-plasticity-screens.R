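# Expression fixture with exact ancestor states: log2 values chosen per gene.
# Columns: AC and AS in both diets.
anc_expr <- function(lAC_cad, lAC_salt, lAS_cad, lAS_salt) {
  n <- length(lAC_cad)
  E <- 1e-4 * 2^cbind(AC_cadmium = lAC_cad, AC_salt = lAC_salt,
                      AS_cadmium = lAS_cad, AS_salt = lAS_salt)
  rownames(E) <- paste0("g", seq_len(n))
  design <- data.frame(
    sample_id = colnames(E),
    population_id = rep(c("AC", "AS"), each = 2),
    regime = rep(c("AC", "AS"), each = 2),
    replicate = 0L,
    diet = rep(c("cadmium", "salt"), 2),
    block = 6L, stringsAsFactors = FALSE
  )
  list(expr = expr_from_E(E), design = design)
}

test_that("increased-plasticity screen applies both criteria strictly", {
  # g1: optima differ by 1, ancestor plasticities 0.2 / 0.3 -> in, Y = +1
  # g2: optima differ by 0.3 -> out by criterion (i)
  # g3: AC plasticity 0.6 with D = 1 -> out by criterion (ii)
  fx <- anc_expr(lAC_cad = c(1, 0.3, 1.0),
                 lAC_salt = c(0.8, 0.3, 0.4),
                 lAS_cad = c(0.3, 0, 0.2),
                 lAS_salt = c(0, 0, 0))
  set <- screen_increased(fx$expr, fx$design)
  expect_equal(set$gene_id, "g1")
  expect_equal(set$polarity, 1L)
})

test_that("decreased-plasticity screen needs consistent O-vs-N direction", {
  # g1: O-N diffs +0.5/+0.6, optima diff 0.1 -> in
  # g2: O-N diffs +0.5/-0.6 -> out (opposite directions)
  # g3: optima diff 0.3 with min O-N 0.5 -> out (0.3 >= 0.25)
  fx <- anc_expr(lAC_cad = c(0.5, 0.5, 0.8),   # O_cad
                 lAC_salt = c(-0.5, 0.7, 0.0), # N_salt
                 lAS_cad = c(0.0, 0.0, 0.3),   # N_cad
                 lAS_salt = c(0.4, 0.1, 0.5))  # O_salt
  set <- screen_decreased(fx$expr, fx$design)
  expect_equal(set$gene_id, "g1")
})

test_that("screens recover the planted gene classes", {
  sim <- small_sim()
  tr <- sim$truth$genes
  expr <- normalize_expression(sim$counts)
  inc <- screen_increased(expr, sim$design)
  dec <- screen_decreased(expr, sim$design)
  inc_true <- tr$gene_id[tr$class == "increased"]
  dec_true <- tr$gene_id[tr$class == "decreased"]
  expect_gt(mean(inc_true %in% inc$gene_id), 0.9)
  expect_gt(mean(dec_true %in% dec$gene_id), 0.9)
  expect_gt(mean(inc$gene_id %in% inc_true), 0.8)
  expect_gt(mean(dec$gene_id %in% dec_true), 0.8)
  # the within-diet reference reading also recovers the planted class
  inc_wd <- screen_increased(expr, sim$design, reference = "within_diet")
  expect_gt(mean(inc_true %in% inc_wd$gene_id), 0.9)
})

test_that("plasticity scores respond to polarity and diet labels as defined", {
  sim <- small_sim()
  expr <- normalize_expression(sim$counts)
  set <- screen_increased(expr, sim$design)
  sc <- polarized_plasticity_score(expr, sim$design, set)
  flipped_set <- set
  flipped_set$polarity <- -set$polarity
  sc_flip <- polarized_plasticity_score(expr, sim$design, flipped_set)
  expect_equal(sc_flip$score, -sc$score)

  abs_sc <- absolute_plasticity_score(expr, sim$design, set)
  expect_equal(absolute_plasticity_score(expr, sim$design, flipped_set)$score,
               abs_sc$score)
  swapped <- sim$design
  swapped$diet <- ifelse(swapped$diet == "cadmium", "salt", "cadmium")
  expect_equal(absolute_plasticity_score(expr, swapped, set)$score, abs_sc$score)
  expect_error(polarized_plasticity_score(expr, sim$design, set[0, ]), "empty")
})

test_that("Phi hits its anchor points and flags out-of-range values", {
  # 2 genes; a focal population whose E equals O (g1) and N (g2) in cadmium
  samples <- c("AC_cadmium", "AC_salt", "AS_cadmium", "AS_salt",
               "P_cadmium", "P_salt")
  E <- matrix(1e-4 * c(2, 1, 4, 3,   2, 2,     # g1: E=O(cad), mid(salt)
                       6, 2, 8, 4,   8, 3,     # g2: E=N(cad), mid(salt)
                       1, 2, 5, 6,   9, 4),    # g3: E outside [O,N] in cadmium
              nrow = 3, byrow = TRUE, dimnames = list(paste0("g", 1:3), samples))
  design <- data.frame(
    sample_id = samples,
    population_id = c("AC", "AC", "AS", "AS", "P", "P"),
    regime = c("AC", "AC", "AS", "AS", "Cad", "Cad"),
    replicate = c(0L, 0L, 0L, 0L, 1L, 1L), diet = rep(c("cadmium", "salt"), 3),
    block = c(6L, 6L, 6L, 6L, 1L, 1L), stringsAsFactors = FALSE
  )
  set <- structure(data.frame(gene_id = paste0("g", 1:3), polarity = 1L), name = "s")
  phi <- adaptive_distance(expr_from_E(E), design, set, populations = "P")
  cad <- phi$per_gene[phi$per_gene$diet == "cadmium", ]
  expect_equal(cad$phi[cad$gene_id == "g1"], 0)
  expect_equal(cad$phi[cad$gene_id == "g2"], 1)
  expect_equal(cad$phi[cad$gene_id == "g3"], 2)    # (9-1)/(5-1)
  expect_true(cad$out_of_range[cad$gene_id == "g3"])
  salt <- phi$per_gene[phi$per_gene$diet == "salt", ]
  # g1 salt: O = AS_salt = 3, N = AC_salt = 1, E = 2 -> 0.5
  expect_equal(salt$phi[salt$gene_id == "g1"], 0.5)
})

test_that("Phi is affine-invariant and drops genes with N == O", {
  fx_samples <- c("AC_cadmium", "AC_salt", "AS_cadmium", "AS_salt", "P_cadmium", "P_salt")
  set.seed(2)
  E <- matrix(abs(rnorm(12, 1e-3, 1e-4)), nrow = 2,
              dimnames = list(c("g1", "g2"), fx_samples))
  design <- data.frame(
    sample_id = fx_samples, population_id = c("AC", "AC", "AS", "AS", "P", "P"),
    regime = c("AC", "AC", "AS", "AS", "Temp", "Temp"),
    replicate = c(0L, 0L, 0L, 0L, 1L, 1L), diet = rep(c("cadmium", "salt"), 3),
    block = c(6L, 6L, 6L, 6L, 1L, 1L), stringsAsFactors = FALSE
  )
  set <- structure(data.frame(gene_id = c("g1", "g2"), polarity = 1L), name = "s")
  phi1 <- adaptive_distance(expr_from_E(E), design, set, populations = "P")
  phi2 <- adaptive_distance(expr_from_E(3.7 * E + 0.01), design, set, populations = "P")
  expect_equal(phi1$per_gene$phi, phi2$per_gene$phi, tolerance = 1e-9)

  E_eq <- E
  E_eq["g2", "AS_cadmium"] <- E_eq["g2", "AC_cadmium"]   # N == O in cadmium
  expect_warning(
    phi3 <- adaptive_distance(expr_from_E(E_eq), design, set, populations = "P"),
    "N == O")
  expect_false("g2" %in% phi3$per_gene$gene_id[phi3$per_gene$diet == "cadmium"])
  expect_true("g2" %in% phi3$per_gene$gene_id[phi3$per_gene$diet == "salt"])
})

test_that("regime ANOVA partitions variance exactly and handles degeneracy", {
  scores <- data.frame(regime = rep(c("Cad", "Salt", "Temp", "Spatial"), each = 5),
                       score = 0)
  deg <- regime_anova_tukey(scores)
  expect_equal(deg$p, 1)
  expect_equal(deg$var_fraction, 0)

  set.seed(3)
  scores$score <- rep(c(0, 0, 1, 1), each = 5) + rnorm(20, 0, 0.1)
  res <- regime_anova_tukey(scores)
  ss_tot <- sum((scores$score - mean(scores$score))^2)
  ss_within <- sum(unlist(tapply(scores$score, scores$regime,
                                 function(x) (x - mean(x))^2)))
  expect_equal(res$var_fraction, 1 - ss_within / ss_tot, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)
  # heterogeneous-vs-homogeneous pairs significant, within-class pairs not
  tk <- res$tukey
  within <- tk$pair %in% c("Salt-Cad", "Temp-Spatial", "Spatial-Temp", "Cad-Salt")
  expect_true(all(tk$p_adj[within] > 0.2))
  expect_true(all(tk$p_adj[!within] < 0.01))
  expect_error(regime_anova_tukey(scores[-1, ]), "unbalanced")
})

test_that("Tukey p-values are near 1 under the null", {
  set.seed(4)
  null_max_sig <- replicate(20, {
    scores <- data.frame(regime = rep(c("Cad", "Salt", "Temp", "Spatial"), each = 5),
                         score = 1 + rnorm(20, 0, 0.1))
    min(regime_anova_tukey(scores)$tukey$p_adj)
  })
  expect_gt(mean(null_max_sig > 0.05), 0.85)
})

test_that("heterogeneity LRT has unit df, calibrated null and high power", {
  blocks <- rep(1:5, 4)
  regimes <- rep(c("Cad", "Salt", "Temp", "Spatial"), each = 5)
  set.seed(5)
  p_null <- replicate(200, {
    sc <- data.frame(regime = regimes, block = blocks, score = rnorm(20))
    heterogeneity_test(sc)$p
  })
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)
  p_alt <- replicate(100, {
    eff <- ifelse(regimes %in% c("Temp", "Spatial"), 1, 0)
    sc <- data.frame(regime = regimes, block = blocks, score = eff + rnorm(20, 0, 0.1))
    heterogeneity_test(sc)$p
  })
  expect_gt(mean(p_alt < 0.01), 0.95)
  sc <- data.frame(regime = regimes, block = blocks, score = rnorm(20))
  expect_equal(heterogeneity_test(sc)$df, 1)
})
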