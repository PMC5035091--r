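# Long allele table for hand-built sites.
allele_rows <- function(gene, site, pos, sample_ids, a, b) {
  data.frame(gene_id = gene, site_id = site, position = pos,
             sample_id = sample_ids, a_count = as.integer(a),
             b_count = as.integer(b), stringsAsFactors = FALSE)
}

test_that("site down-sampling equalizes coverage within blocks exactly", {
  sim <- small_sim()
  ds <- downsample_sites(sim$alleles, sim$design, seed = 9L)
  expect_identical(ds, downsample_sites(sim$alleles, sim$design, seed = 9L))
  tot_in <- sim$alleles$a_count + sim$alleles$b_count
  tot_out <- ds$a_count + ds$b_count
  expect_true(all(tot_out <= tot_in))
  block <- sim$design$block[match(ds$sample_id, sim$design$sample_id)]
  grp <- paste(ds$site_id, block)
  expect_true(all(tapply(tot_out, grp, function(x) length(unique(x))) == 1))
})

test_that("site down-sampling keeps monomorphic sites monomorphic", {
  samples <- c("A_cadmium", "A_salt")
  al <- allele_rows("g1", "s1", 10L, samples, a = c(8, 4), b = c(0, 0))
  design <- tiny_design(samples)
  ds <- downsample_sites(al, design, seed = 1L)
  expect_equal(ds$a_count, c(4L, 4L))
  expect_equal(ds$b_count, c(0L, 0L))
  # all already at the minimum -> identity
  al_eq <- allele_rows("g1", "s1", 10L, samples, a = c(3, 2), b = c(1, 2))
  expect_equal(downsample_sites(al_eq, design, seed = 1L)$a_count, c(3L, 2L))
})

test_that("zero-coverage samples zero out the whole block for the site", {
  samples <- c("A_cadmium", "A_salt")
  al <- allele_rows("g1", "s1", 10L, samples, a = c(8, 0), b = c(2, 0))
  ds <- downsample_sites(al, tiny_design(samples), seed = 1L)
  expect_true(all(ds$a_count == 0L & ds$b_count == 0L))
  expect_equal(attr(ds, "zeroed")$site_id, "s1")
})

test_that("site down-sampling matches hypergeometric moments", {
  samples <- c("A_cadmium", "A_salt")
  al <- allele_rows("g1", "s1", 10L, samples, a = c(6, 3), b = c(4, 2))
  design <- tiny_design(samples)
  n_rep <- 10000
  draws <- vapply(seq_len(n_rep), function(s) {
    downsample_sites(al, design, seed = s)$a_count[1]
  }, numeric(1))
  v <- 5 * 0.6 * 0.4 * (10 - 5) / 9
  expect_lt(abs(mean(draws) - 3), 3 * sqrt(v / n_rep))
})

test_that("site screening applies the three criteria with strict bounds", {
  design <- canonical_design()
  cad_samples <- design$sample_id[design$regime == "Cad"]
  mk_site <- function(gene, site, pos, a_each, b_each) {
    allele_rows(gene, site, pos, cad_samples, rep(a_each, 10), rep(b_each, 10))
  }
  al <- rbind(
    mk_site("g1", "g1_s1", 5L, 6, 5),    # n = 110 > 100, p = 6/11 -> kept
    mk_site("g2", "g2_s1", 5L, 10, 1),   # 2pq = 0.15 < 0.2 -> dropped
    mk_site("g3", "g3_s1", 5L, 5, 5)     # n = 100 exactly -> dropped (strict)
  )
  kept <- screen_sites(al, design, "Cad")
  expect_equal(kept$gene_id, "g1")
  expect_equal(kept$n_i, 110)
  expect_equal(kept$p_i, 6 / 11)

  # criterion (iii): a site carrying under half the gene's counts is dropped
  al2 <- rbind(mk_site("g4", "g4_s1", 5L, 7, 7),     # n = 140
               mk_site("g4", "g4_s2", 9L, 16, 15))   # n = 310 > half of 450
  kept2 <- screen_sites(al2, design, "Cad")
  expect_equal(kept2$site_id, "g4_s2")
})

test_that("the most informative site wins, ties broken by position", {
  stats <- data.frame(
    regime = "Cad", gene_id = c("g1", "g1", "g2", "g2"),
    site_id = c("a", "b", "c", "d"), position = c(10L, 2L, 7L, 3L),
    n_i = c(100, 100, 100, 100), p_i = 0.5,
    informativeness = c(25.0, 24.9, 20, 20), stringsAsFactors = FALSE
  )
  pick <- pick_informative_site(stats)
  expect_equal(pick$site_id[pick$gene_id == "g1"], "a")   # higher informativeness
  expect_equal(pick$site_id[pick$gene_id == "g2"], "d")   # tie -> lower position
  single <- stats[1, ]
  expect_equal(pick_informative_site(single)$site_id, "a")
})

test_that("CMH statistic matches its defining formula and mantelhaen.test", {
  # single extreme stratum: hand-evaluated statistic
  one <- cmh_test(array(c(10, 0, 0, 10), c(2, 2, 1)))
  expect_equal(one$statistic, 15.39, tolerance = 1e-3)
  expect_equal(one$p, 8.7e-5, tolerance = 1e-2)

  # exact null with clamped correction
  null5 <- cmh_test(array(rep(5, 20), c(2, 2, 5)))
  expect_equal(null5$statistic, 0)
  expect_equal(null5$p, 1)

  set.seed(21)
  for (i in 1:100) {
    tabs <- random_strat_tables(5)
    got <- cmh_test(tabs)
    oracle <- cmh_formula_oracle(tabs)
    expect_equal(got$statistic, oracle$statistic, tolerance = 1e-6)
    expect_equal(got$p, oracle$p, tolerance = 1e-8)
    # mantelhaen.test applies the same correction but without clamping at
    # zero; the two agree whenever the corrected deviation is positive
    if (got$statistic > 1e-8) {
      mh <- mantelhaen.test(tabs, correct = TRUE)
      expect_equal(got$statistic, unname(mh$statistic), tolerance = 1e-6)
      expect_equal(got$p, mh$p.value, tolerance = 1e-8)
    }
  }
})

test_that("CMH is invariant to swapping both row and both column labels", {
  set.seed(22)
  for (i in 1:20) {
    tabs <- random_strat_tables(5)
    swapped <- tabs[2:1, 2:1, , drop = FALSE]
    expect_equal(cmh_test(tabs)$statistic, cmh_test(swapped)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("CMH skips degenerate strata and errors when all are degenerate", {
  tabs <- array(c(10, 0, 0, 10, 1, 0, 0, 0), c(2, 2, 2))  # second stratum n = 1
  expect_equal(cmh_test(tabs)$statistic,
               cmh_test(array(c(10, 0, 0, 10), c(2, 2, 1)))$statistic)
  expect_error(cmh_test(array(c(1, 0, 0, 0), c(2, 2, 1))), "degenerate")
})

test_that("the allelic scan detects planted bias and controls the null", {
  sim <- small_sim()
  ds <- downsample_sites(sim$alleles, sim$design, seed = 2L)
  scan <- allelic_scan(ds, sim$design, "Salt")
  tr <- sim$truth$genes
  biased <- scan$result$gene_id %in% tr$gene_id[tr$allelic_bias != 0]
  expect_gt(mean(scan$result$allelic_plastic[biased]), 0.8)
  expect_lt(mean(scan$result$allelic_plastic[!biased]), 0.03)
  expect_true(all(scan$result$allelic_plastic == (scan$result$p < scan$p_thr)))
  # empty allele table -> empty result
  empty <- allelic_scan(sim$alleles[0, ], sim$design, "Salt")
  expect_equal(nrow(empty$result), 0L)
})

test_that("null CMH p-values are not anti-conservative", {
  cfg <- sim_config(n_genes = 1200, r_plastic = 0, r_nonplastic = 0, seed = 31L)
  sim <- simulate_experiment(cfg)
  ds <- downsample_sites(sim$alleles, sim$design, seed = 1L)
  scan <- allelic_scan(ds, sim$design, "Cad")
  p <- scan$result$p
  expect_gt(length(p), 1000)
  # empirical CDF must not exceed the uniform (one-sided comparison at 3 SE)
  for (a in c(0.01, 0.05, 0.1)) {
    expect_lt(mean(p < a), a + 3 * sqrt(a * (1 - a) / length(p)))
  }
})

test_that("diff_f is the difference of the two fractions over the joint universe", {
  sim <- small_sim()
  expr <- normalize_expression(sim$counts)
  ds <- downsample_sites(sim$alleles, sim$design, seed = 2L)
  scan <- allelic_scan(ds, sim$design, "Salt")
  de <- fit_gene_models(expr, sim$design, "one_regime_diet_effect",
                        regime = "Salt", counts = sim$counts)
  enr <- enrichment_diff_f(scan, de)
  expect_equal(enr$diff_f, enr$f1 - enr$f2)
  expect_true(all(c(enr$f1, enr$f2) >= 0 & c(enr$f1, enr$f2) <= 1))
  expect_true(all(enr$universe %in% scan$result$gene_id))
  expect_true(all(enr$universe %in% de$gene_id))
})

test_that("permutation p-value is capped at 1 and detects planted enrichment", {
  cfg <- sim_config(n_genes = 800, r_plastic = 0.45, r_nonplastic = 0.05, seed = 17L)
  sim <- simulate_experiment(cfg)
  expr <- normalize_expression(sim$counts)
  ds <- downsample_sites(sim$alleles, sim$design, seed = 1L)
  scan <- allelic_scan(ds, sim$design, "Salt")
  de <- fit_gene_models(expr, sim$design, "one_regime_diet_effect",
                        regime = "Salt", counts = sim$counts)
  pn <- permutation_null(scan, de, n_perm = 400L, seed = 3L)
  expect_lt(pn$p_perm, 0.01)
  expect_gt(pn$diff_f_observed, 0)
  # permutations conserve the per-diet and per-allele totals by construction;
  # n_perm = 1 with a permuted value >= observed caps at 1
  fake <- scan
  fake$result$allelic_plastic <- rep(FALSE, nrow(fake$result))
  fake$result$allelic_plastic[1] <- TRUE
  pn1 <- permutation_null(fake, de, n_perm = 1L, seed = 4L)
  expect_equal(pn1$p_perm, 1)
})

test_that("a threefold prevalence ratio is detected in most data sets", {
  pp <- vapply(1:15, function(i) {
    sim <- simulate_experiment(sim_config(n_genes = 800, r_plastic = 0.3,
                                          r_nonplastic = 0.1, seed = 500L + i))
    expr <- normalize_expression(sim$counts)
    ds <- downsample_sites(sim$alleles, sim$design, seed = 600L + i)
    scan <- allelic_scan(ds, sim$design, "Salt")
    de <- fit_gene_models(expr, sim$design, "one_regime_diet_effect",
                          regime = "Salt", counts = sim$counts)
    permutation_null(scan, de, n_perm = 300L, seed = 700L + i)$p_perm
  }, numeric(1))
  expect_gte(mean(pp < 0.05), 0.9)
})

test_that("direction alignment handles constructed sign vectors", {
  sim <- small_sim()
  ds <- downsample_sites(sim$alleles, sim$design, seed = 2L)
  scan <- allelic_scan(ds, sim$design, "Salt")
  al <- direction_alignment(scan, sim$snp, seed = 5L)
  expect_true(abs(al$mean_sign) <= 1)
  expect_lte(al$ci[1], al$ci[2])
  # planted 90% alignment: bootstrap CI excludes zero
  expect_true(al$excludes_zero)
  expect_gt(al$mean_sign, 0.5)

  # balanced +-1 signs: CI overlaps zero (built by neutralizing the SNP table)
  snp_flip <- sim$snp
  set.seed(6)
  snp_flip$direction <- sample(c(-1L, 1L), nrow(snp_flip), replace = TRUE)
  al_null <- direction_alignment(scan, snp_flip, seed = 7L)
  expect_false(al_null$excludes_zero)
  expect_error(direction_alignment(scan, sim$snp[0, ], seed = 1L), "fewer than 2")
})

test_that("SNP-region enrichment matches the 2x2 chi-square and flags margins", {
  # [[30,70],[10,90]]: known chi-square 12.5 on one df
  snp <- data.frame(
    snp_id = sprintf("s%d", 1:200), gene_id = sprintf("g%d", 1:200),
    region = "exon",
    diff_q = rep(c(1e-6, 1), times = c(100, 100)),
    direction = 1L, stringsAsFactors = FALSE
  )
  de_set <- structure(
    data.frame(gene_id = sprintf("g%d", c(1:30, 101:110)), polarity = 1L),
    name = "de")
  snp$region <- "exon"
  universe <- sprintf("g%d", 1:200)
  snp3 <- rbind(snp,
                transform(snp, region = "intron", snp_id = paste0(snp_id, "i")),
                transform(snp, region = "flank1kb", snp_id = paste0(snp_id, "f")))
  res <- snp_region_enrichment(de_set, snp3, universe)
  expect_equal(res$chi2, rep(12.5, 3), tolerance = 1e-10)
  expect_equal(res$df, rep(1, 3))

  # all genes DE-significant -> degenerate margin
  de_all <- structure(data.frame(gene_id = universe, polarity = 1L), name = "de")
  expect_error(snp_region_enrichment(de_all, snp3, universe), "degenerate margin")
})

test_that("SNP-region enrichment type-I rate is nominal under independence", {
  set.seed(33)
  n_rep <- 200
  pvals <- replicate(n_rep, {
    n <- 300
    snp <- data.frame(snp_id = sprintf("s%d", 1:n), gene_id = sprintf("g%d", 1:n),
                      region = "exon", diff_q = ifelse(runif(n) < 0.3, 1e-6, 0.5),
                      direction = 1L, stringsAsFactors = FALSE)
    de_set <- structure(
      data.frame(gene_id = sprintf("g%d", which(runif(n) < 0.2)), polarity = 1L),
      name = "de")
    out <- tryCatch(
      snp_region_enrichment(de_set, snp, sprintf("g%d", 1:n))[1, "p"],
      error = function(e) NA_real_)
    out
  })
  pvals <- pvals[!is.na(pvals)]
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(pvals)) + 0.01)
})
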