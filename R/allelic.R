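#' Down-sample allele counts to equal site coverage within blocks
#'
#' For every site and block, each sample's site coverage (`a + b`) is
#' reduced without replacement (hypergeometric over the two alleles) to the
#' minimum coverage among that block's samples, equalizing the power to
#' detect allelic bias.  If any sample of a block has zero coverage at a
#' site, all of that block's samples are set to zero for the site and the
#' (site, block) pair is flagged.
#'
#' @param alleles long allele-count table (`gene_id`, `site_id`, `position`,
#'   `sample_id`, `a_count`, `b_count`).
#' @param design design table supplying the block of each sample.
#' @param seed integer seed; deterministic given the seed.
#' @return Allele table of the same shape; attribute `"zeroed"` lists
#'   flagged (site_id, block) pairs.
#' @export
downsample_sites <- function(alleles, design, seed = 1L) {
  validate_alleles(alleles, design)
  set.seed(seed)
  block <- design$block[match(alleles$sample_id, design$sample_id)]
  tot <- alleles$a_count + alleles$b_count
  grp <- paste(alleles$site_id, block)
  target <- stats::ave(tot, grp, FUN = min)
  zero_grp <- unique(grp[target == 0 & tot > 0])
  a <- alleles$a_count
  b <- alleles$b_count
  zero_rows <- grp %in% zero_grp
  a[zero_rows] <- 0L
  b[zero_rows] <- 0L
  shrink <- which(!zero_rows & tot > target)
  if (length(shrink)) {
    a[shrink] <- stats::rhyper(length(shrink),
                               m = alleles$a_count[shrink],
                               n = alleles$b_count[shrink],
                               k = target[shrink])
    b[shrink] <- target[shrink] - a[shrink]
  }
  out <- alleles
  out$a_count <- as.integer(a)
  out$b_count <- as.integer(b)
  if (length(zero_grp)) {
    parts <- do.call(rbind, strsplit(zero_grp, " (?=[^ ]+$)", perl = TRUE))
    attr(out, "zeroed") <- data.frame(site_id = parts[, 1],
                                      block = as.integer(parts[, 2]),
                                      stringsAsFactors = FALSE)
  } else {
    attr(out, "zeroed") <- data.frame(site_id = character(0), block = integer(0))
  }
  out
}

#' Screen polymorphic sites within one regime
#'
#' Site statistics over a regime's 10 samples (5 replicate populations x 2
#' diets): total count `n_i`, mean allele-a frequency `p_i` (average of the
#' per-sample frequencies over samples with coverage), and informativeness
#' `n_i * p_i * q_i`.  A site is kept when (i) its average diversity
#' `2 p_i q_i > div_thr`, (ii) `n_i > n_thr` (strict), and (iii) `n_i` is at
#' least half of the gene's total count across the regime's samples (summed
#' over the gene's sites in the allele table).
#'
#' @param alleles (down-sampled) long allele table.
#' @param design design table.
#' @param regime one evolved regime.
#' @param div_thr diversity threshold (default 0.20).
#' @param n_thr total-count threshold (default 100).
#' @return `data.frame` of surviving sites: `regime`, `gene_id`, `site_id`,
#'   `position`, `n_i`, `p_i`, `informativeness`.
#' @export
screen_sites <- function(alleles, design, regime, div_thr = 0.20, n_thr = 100) {
  samples <- design$sample_id[design$regime == regime]
  x <- alleles[alleles$sample_id %in% samples, ]
  if (nrow(x) == 0L) {
    return(data.frame(regime = character(0), gene_id = character(0),
                      site_id = character(0), position = integer(0),
                      n_i = numeric(0), p_i = numeric(0),
                      informativeness = numeric(0)))
  }
  cov <- x$a_count + x$b_count
  freq <- ifelse(cov > 0, x$a_count / cov, NA_real_)
  key <- factor(x$site_id, levels = unique(x$site_id))
  n_i <- as.numeric(tapply(cov, key, sum))
  p_i <- as.numeric(tapply(freq, key, mean, na.rm = TRUE))
  p_i[is.nan(p_i)] <- NA_real_
  first <- !duplicated(key)
  sites <- data.frame(
    regime = regime,
    gene_id = x$gene_id[first],
    site_id = as.character(levels(key)),
    position = x$position[first],
    n_i = n_i, p_i = p_i,
    stringsAsFactors = FALSE
  )
  gene_total <- tapply(sites$n_i, sites$gene_id, sum)
  sites$informativeness <- sites$n_i * sites$p_i * (1 - sites$p_i)
  keep <- !is.na(sites$p_i) &
    2 * sites$p_i * (1 - sites$p_i) > div_thr &
    sites$n_i > n_thr &
    sites$n_i >= 0.5 * as.numeric(gene_total[sites$gene_id])
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose the most informative site per gene
#'
#' One site per (regime, gene): the surviving site with the highest
#' informativeness `n_i * p_i * q_i`; exact ties broken by smallest genomic
#' position.
#'
#' @param sites output of [screen_sites()].
#' @return Subset of `sites` with one row per gene.
#' @export
pick_informative_site <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  ord <- order(sites$gene_id, -sites$informativeness, sites$position)
  x <- sites[ord, , drop = FALSE]
  out <- x[!duplicated(x$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Vectorized CMH statistic across genes.  Arguments are gene x stratum
## matrices: a = top-left cell, r1 = first row total, c1 = first column
## total, n = stratum total.  Strata with n <= 1 are skipped.
cmh_stat_matrix <- function(a, r1, c1, n, correct = TRUE) {
  valid <- n > 1
  E <- ifelse(valid, r1 * c1 / n, 0)
  V <- ifelse(valid, r1 * (n - r1) * c1 * (n - c1) / (n^2 * (n - 1)), 0)
  sum_dev <- rowSums((a - E) * valid)
  sum_V <- rowSums(V)
  dev <- abs(sum_dev)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- ifelse(sum_V > 0, dev^2 / sum_V, NA_real_)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p = p)
}

#' Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' One-df CMH chi-square for association between diet and allele across K
#' strata (replicate populations), with the 0.5 continuity correction
#' clamped at zero:
#' `chi2 = (max(|sum_k (a_k - E_k)| - 1/2, 0))^2 / sum_k V_k`
#' with `E_k = row1_k col1_k / n_k` and
#' `V_k = row1_k row2_k col1_k col2_k / (n_k^2 (n_k - 1))`.  Strata with
#' total `n_k <= 1` are skipped.
#'
#' @param tables 2 x 2 x K array (rows = diets, columns = alleles).
#' @param correct apply the continuity correction (default `TRUE`).
#' @return List with `statistic` and `p` (upper chi-square-1 tail).
#' @export
cmh_test <- function(tables, correct = TRUE) {
  if (length(dim(tables)) == 2L) tables <- array(tables, c(2, 2, 1))
  stopifnot(length(dim(tables)) == 3L, all(dim(tables)[1:2] == 2))
  a <- matrix(tables[1, 1, ], nrow = 1)
  r1 <- matrix(tables[1, 1, ] + tables[1, 2, ], nrow = 1)
  c1 <- matrix(tables[1, 1, ] + tables[2, 1, ], nrow = 1)
  n <- matrix(apply(tables, 3, sum), nrow = 1)
  if (all(n <= 1)) stop("all strata degenerate (total <= 1)")
  res <- cmh_stat_matrix(a, r1, c1, n, correct = correct)
  list(statistic = unname(res$statistic), p = unname(res$p))
}

#' Allelic-plasticity scan for one regime
#'
#' Full per-gene scan: screen sites, choose the most informative site per
#' gene, and test each gene for a between-diet change in allelic bias with
#' a CMH test stratified by replicate population (the two diet assays of a
#' population form one 2x2 stratum of diets x alleles).
#'
#' @param alleles (down-sampled) long allele table.
#' @param design design table.
#' @param regime one evolved regime.
#' @param p_thr significance threshold for the `allelic_plastic` flag
#'   (default 0.01, strict).
#' @param div_thr,n_thr site-screen thresholds (see [screen_sites()]).
#' @param correct CMH continuity correction.
#' @return Object of class `allelic_scan`: list with `result` (per-gene
#'   `data.frame`: `gene_id`, `site_id`, `statistic`, `p`,
#'   `allelic_plastic`), `counts` (gene x population matrices `a_cad`,
#'   `b_cad`, `a_salt`, `b_salt` of the chosen sites), `regime`, `p_thr`.
#' @export
allelic_scan <- function(alleles, design, regime, p_thr = 0.01,
                         div_thr = 0.20, n_thr = 100, correct = TRUE) {
  sites <- screen_sites(alleles, design, regime, div_thr = div_thr, n_thr = n_thr)
  chosen <- pick_informative_site(sites)
  empty <- list(
    result = data.frame(gene_id = character(0), site_id = character(0),
                        statistic = numeric(0), p = numeric(0),
                        allelic_plastic = logical(0)),
    counts = NULL, regime = regime, p_thr = p_thr
  )
  class(empty) <- "allelic_scan"
  if (nrow(chosen) == 0L) return(empty)

  pops <- sort(unique(design$population_id[design$regime == regime]))
  x <- alleles[alleles$site_id %in% chosen$site_id, ]
  x <- x[x$sample_id %in% design$sample_id[design$regime == regime], ]
  x$population_id <- design$population_id[match(x$sample_id, design$sample_id)]
  x$diet <- design$diet[match(x$sample_id, design$sample_id)]
  gi <- match(x$site_id, chosen$site_id)
  pi_ <- match(x$population_id, pops)
  mk <- function() matrix(0, nrow = nrow(chosen), ncol = length(pops),
                          dimnames = list(chosen$gene_id, pops))
  a_cad <- mk(); b_cad <- mk(); a_salt <- mk(); b_salt <- mk()
  cad <- x$diet == "cadmium"
  a_cad[cbind(gi[cad], pi_[cad])] <- x$a_count[cad]
  b_cad[cbind(gi[cad], pi_[cad])] <- x$b_count[cad]
  a_salt[cbind(gi[!cad], pi_[!cad])] <- x$a_count[!cad]
  b_salt[cbind(gi[!cad], pi_[!cad])] <- x$b_count[!cad]

  res <- cmh_stat_matrix(
    a = a_cad,
    r1 = a_cad + b_cad,
    c1 = a_cad + a_salt,
    n = a_cad + b_cad + a_salt + b_salt,
    correct = correct
  )
  out <- list(
    result = data.frame(
      gene_id = chosen$gene_id, site_id = chosen$site_id,
      statistic = res$statistic, p = res$p,
      allelic_plastic = !is.na(res$p) & res$p < p_thr,
      stringsAsFactors = FALSE
    ),
    counts = list(a_cad = a_cad, b_cad = b_cad, a_salt = a_salt, b_salt = b_salt),
    regime = regime, p_thr = p_thr, correct = correct
  )
  class(out) <- "allelic_scan"
  out
}

#' @export
print.allelic_scan <- function(x, ...) {
  cat(sprintf("allelic_scan (%s): %d genes, %d allelic-plastic at p < %g\n",
              x$regime, nrow(x$result), sum(x$result$allelic_plastic), x$p_thr))
  invisible(x)
}

#' Enrichment of allelic plasticity among abundance-plastic genes
#'
#' Over the universe of genes present in both the allelic scan and the
#' abundance (differential-expression) analysis, computes the fraction of
#' allelic-plastic genes among genes with significant abundance plasticity
#' (`f1`), among genes without (`f2`), and their difference
#' `diff_f = f1 - f2`.
#'
#' @param scan an [allelic_scan()] object.
#' @param de per-gene model fit of the regime's diet effect
#'   ([fit_gene_models()] with `one_regime_diet_effect`), supplying raw
#'   `p_diet`.
#' @param abund_p_thr abundance-plasticity p threshold (default 0.05,
#'   strict).
#' @return List with `f1`, `f2`, `diff_f`, `n1`, `n2`, `universe`.
#' @export
enrichment_diff_f <- function(scan, de, abund_p_thr = 0.05) {
  de_ok <- de[de$tested & !is.na(de$p_diet), ]
  universe <- intersect(scan$result$gene_id, de_ok$gene_id)
  if (length(universe) == 0L) stop("empty gene universe")
  allelic <- scan$result$allelic_plastic[match(universe, scan$result$gene_id)]
  abund <- de_ok$p_diet[match(universe, de_ok$gene_id)] < abund_p_thr
  if (!any(abund) || all(abund)) {
    stop("empty abundance-plasticity stratum; diff_f undefined")
  }
  f1 <- mean(allelic[abund])
  f2 <- mean(allelic[!abund])
  list(f1 = f1, f2 = f2, diff_f = f1 - f2,
       n1 = sum(abund), n2 = sum(!abund), universe = universe)
}

## diff_f given logical flags over a universe
diff_f_of <- function(allelic, abund) mean(allelic[abund]) - mean(allelic[!abund])

#' Permutation null for the allelic-plasticity enrichment
#'
#' Tests whether `diff_f` (the excess of allelic plasticity among
#' abundance-plastic genes) exceeds chance.  Each permutation relabels the
#' reads of every gene's chosen site across diets within each population:
#' the cadmium count of allele a is redrawn from the central hypergeometric
#' distribution conditioned on the site's per-diet totals and per-allele
#' totals (the exact distribution of a uniformly random read relabelling).
#' Genes are re-tested by CMH; because chance significants are fewer than
#' the observed ones, randomly chosen genes are promoted to "significant"
#' until the observed count is matched (or demoted if the pseudo-count
#' exceeds it).  `diff_f` is recomputed against the fixed observed
#' abundance-plasticity flags, and
#' `p_perm = min(1, 2 (#\{diff_f_perm >= diff_f_obs\} + 1) / (n_perm + 1))`.
#'
#' @param scan an [allelic_scan()] object (with counts).
#' @param de abundance model fit (see [enrichment_diff_f()]).
#' @param abund_p_thr abundance-plasticity p threshold.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return List with `p_perm`, `diff_f_observed`, `f1`, `f2`, `n_perm`,
#'   `diff_f_perm` (the null draws), `n_demoted` (permutations where the
#'   pseudo-significant count exceeded the observed one).
#' @export
permutation_null <- function(scan, de, abund_p_thr = 0.05,
                             n_perm = 5000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  obs <- enrichment_diff_f(scan, de, abund_p_thr = abund_p_thr)
  universe <- obs$universe
  idx <- match(universe, scan$result$gene_id)
  de_ok <- de[de$tested & !is.na(de$p_diet), ]
  abund <- de_ok$p_diet[match(universe, de_ok$gene_id)] < abund_p_thr
  n_sig_obs <- sum(scan$result$allelic_plastic[idx])
  if (n_sig_obs > length(universe)) stop("observed significant count exceeds universe")

  a_cad <- scan$counts$a_cad[idx, , drop = FALSE]
  b_cad <- scan$counts$b_cad[idx, , drop = FALSE]
  a_salt <- scan$counts$a_salt[idx, , drop = FALSE]
  b_salt <- scan$counts$b_salt[idx, , drop = FALSE]
  m_a <- a_cad + a_salt          # allele-a total per population
  m_b <- b_cad + b_salt
  k_cad <- a_cad + b_cad         # cadmium-diet total per population
  nr <- nrow(a_cad); nc <- ncol(a_cad)

  set.seed(seed)
  diff_perm <- numeric(n_perm)
  n_demoted <- 0L
  for (it in seq_len(n_perm)) {
    a_cad_p <- matrix(stats::rhyper(nr * nc, m = m_a, n = m_b, k = k_cad),
                      nrow = nr)
    res <- cmh_stat_matrix(
      a = a_cad_p,
      r1 = k_cad,
      c1 = m_a,
      n = m_a + m_b,
      correct = isTRUE(scan$correct)
    )
    sig <- !is.na(res$p) & res$p < scan$p_thr
    n_sig <- sum(sig)
    if (n_sig < n_sig_obs) {
      pool <- which(!sig)
      sig[sample(pool, n_sig_obs - n_sig)] <- TRUE
    } else if (n_sig > n_sig_obs) {
      n_demoted <- n_demoted + 1L
      pool <- which(sig)
      sig[sample(pool, n_sig - n_sig_obs)] <- FALSE
    }
    diff_perm[it] <- diff_f_of(sig, abund)
  }
  p_perm <- min(1, 2 * (sum(diff_perm >= obs$diff_f) + 1) / (n_perm + 1))
  list(p_perm = p_perm, diff_f_observed = obs$diff_f,
       f1 = obs$f1, f2 = obs$f2, n_perm = n_perm,
       diff_f_perm = diff_perm, n_demoted = n_demoted)
}

#' Direction alignment between allelic plasticity and SNP differentiation
#'
#' For genes showing both allelic plasticity (CMH `p < p_thr`) and strong
#' genomic allele-frequency differentiation (`diff_q < diff_q_thr` at the
#' gene's most differentiated SNP), asks whether the allele over-expressed
#' in the cadmium assay is the allele whose genomic frequency is higher in
#' cadmium-selected populations (sign +1) or not (-1).  The mean sign over
#' genes is bootstrapped (resampling genes with replacement); the verdict
#' is whether the percentile confidence interval excludes zero.
#'
#' @param scan an [allelic_scan()] object.
#' @param snp SNP-differentiation table (`direction` = sign of the
#'   cadmium-vs-salt genomic frequency change of allele a).
#' @param diff_q_thr differentiation q threshold (default 0.001, strict).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return List with `signs` (named per-gene vector), `mean_sign`, `ci`
#'   (2.5% and 97.5% percentiles), `excludes_zero`, `n_genes`, `n_boot`.
#' @export
direction_alignment <- function(scan, snp, diff_q_thr = 0.001,
                                n_boot = 2000L, seed = 1L) {
  sig_genes <- scan$result$gene_id[scan$result$allelic_plastic]
  snp_sub <- snp[snp$gene_id %in% sig_genes & snp$diff_q < diff_q_thr, ]
  if (nrow(snp_sub) == 0L) stop("fewer than 2 genes pass both filters")
  snp_sub <- snp_sub[order(snp_sub$gene_id, snp_sub$diff_q), ]
  snp_top <- snp_sub[!duplicated(snp_sub$gene_id), ]

  idx <- match(snp_top$gene_id, rownames(scan$counts$a_cad))
  p_cad <- rowSums(scan$counts$a_cad)[idx] /
    rowSums(scan$counts$a_cad + scan$counts$b_cad)[idx]
  p_salt <- rowSums(scan$counts$a_salt)[idx] /
    rowSums(scan$counts$a_salt + scan$counts$b_salt)[idx]
  allelic_dir <- sign(p_cad - p_salt)
  ok <- allelic_dir != 0 & !is.na(allelic_dir)
  signs <- allelic_dir[ok] * snp_top$direction[ok]
  names(signs) <- snp_top$gene_id[ok]
  if (length(signs) < 2L) stop("fewer than 2 genes pass both filters")

  set.seed(seed)
  boot_means <- vapply(seq_len(n_boot), function(i) {
    mean(sample(signs, replace = TRUE))
  }, numeric(1))
  ci <- stats::quantile(boot_means, c(0.025, 0.975), names = FALSE)
  list(signs = signs, mean_sign = mean(signs), ci = ci,
       excludes_zero = ci[1] > 0 || ci[2] < 0,
       n_genes = length(signs), n_boot = n_boot)
}

#' Enrichment of differential expression among genes with differentiated SNPs
#'
#' Per SNP region category (exon, intron, 1 kb flank), a 2x2 chi-square
#' test (df = 1, no continuity correction) of association between carrying
#' a significantly differentiated SNP in that region and being in the
#' differential-expression gene set.  The universe for each region is the
#' set of genes that have a polymorphic SNP annotated to the region and are
#' present in `universe` (the genes entering the expression analysis);
#' genes with SNPs in several regions enter each relevant test.
#'
#' @param de_set gene screen set of differentially expressed genes.
#' @param snp SNP-differentiation table.
#' @param universe character vector of genes in the expression analysis.
#' @param diff_q_thr differentiation q threshold (default 0.001).
#' @return `data.frame` per region: `region`, `n`, `chi2`, `df`, `p`.
#' @export
snp_region_enrichment <- function(de_set, snp, universe, diff_q_thr = 0.001) {
  regions <- intersect(SNP_REGIONS, unique(snp$region))
  if (length(regions) == 0L) stop("no SNP region categories present")
  rows <- lapply(regions, function(rg) {
    s <- snp[snp$region == rg & snp$gene_id %in% universe, ]
    genes <- unique(s$gene_id)
    if (length(genes) == 0L) stop(sprintf("no genes with SNPs in region %s", rg))
    diffed <- genes %in% unique(s$gene_id[s$diff_q < diff_q_thr])
    de <- genes %in% de_set$gene_id
    tab <- table(factor(diffed, c(TRUE, FALSE)), factor(de, c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      stop(sprintf("degenerate margin in region %s", rg))
    }
    ht <- stats::chisq.test(tab, correct = FALSE)
    data.frame(region = rg, n = length(genes),
               chi2 = unname(ht$statistic), df = unname(ht$parameter),
               p = unname(ht$p.value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
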