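#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  The defaults describe the
#' study conditions every downstream test assumes: 46 samples (four evolved
#' regimes x five replicate populations x two diets in five blocks, plus the
#' three ancestors in block 6), negative-binomial counts around a log-normal
#' baseline, and three planted gene classes besides neutral genes:
#'
#' * `countergradient`: the naive ancestor (GA) is diet-plastic with sign Z
#'   (`delta_diet` log2 units, positive = up in cadmium when Z = +1) and the
#'   evolved Cad-vs-Salt history difference has sign -Z (`delta_hist`).  The
#'   Salt regime (and the salt-adapted ancestor) retains the ancestral
#'   plastic response; the Cad regime (and AC) has lost it.
#' * `increased` (predicted to gain plasticity): the two optima (AC in
#'   cadmium, AS in salt) differ by `delta_int` with sign Y; each ancestor
#'   sits at its own optimum in both diets (low plasticity); the
#'   heterogeneous regimes (Temp, Spatial) are plastic toward each diet's
#'   optimum while each constant regime tracks only its own.
#' * `decreased` (predicted to lose plasticity): the optima coincide, both
#'   ancestors are strongly perturbed (by `delta_diet`, same direction S) in
#'   their foreign diet, constant regimes remain perturbed in the foreign
#'   diet, and the heterogeneous regimes have lost the perturbation.
#'
#' Allele-count sites receive a diet-dependent expression bias (log-odds
#' `allelic_bias`) with probability `r_plastic` for genes that are
#' diet-plastic in the Salt regime and `r_nonplastic` otherwise; allele
#' frequencies are shared between the two diet assays of a population.
#' The SNP table marks a gene's SNPs as strongly differentiated with
#' probability `snp_diff_frac_de` when the gene carries a planted history
#' effect and `snp_diff_frac_null` otherwise; for genes with planted allelic
#' bias the SNP direction agrees with the expression bias with probability
#' `align_frac`.
#'
#' @param n_genes number of genes.
#' @param frac_counter,frac_increased,frac_decreased fractions of genes in
#'   each planted class (remainder neutral).
#' @param baseline_meanlog2,baseline_sdlog2 normal distribution of baseline
#'   log2 expression.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param delta_diet,delta_hist,delta_int planted effect sizes, log2 scale.
#' @param sigma_block SD of per-gene-per-block effects, log2 scale.
#' @param library_size expected total counts per sample.
#' @param n_sites_per_gene allele-count sites per gene.
#' @param site_coverage expected per-sample coverage of each site.
#' @param allele_shape Beta(shape, shape) distribution of gene-level allele
#'   frequencies.
#' @param allele_kappa concentration of per-population frequencies around the
#'   gene-level frequency (larger = less drift between populations).
#' @param r_plastic,r_nonplastic prevalence of planted allelic bias among
#'   diet-plastic and non-plastic genes.
#' @param allelic_bias planted between-diet log-odds shift of allele a.
#' @param snp_diff_frac_de,snp_diff_frac_null fraction of genes whose SNPs
#'   are strongly differentiated (q < 0.001), by history-effect status.
#' @param align_frac fraction of allelically biased genes whose SNP direction
#'   matches the expression bias direction.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       frac_counter = 0.05,
                       frac_increased = 0.05,
                       frac_decreased = 0.05,
                       baseline_meanlog2 = 5,
                       baseline_sdlog2 = 1.5,
                       dispersion = 0.002,
                       delta_diet = 1,
                       delta_hist = 1,
                       delta_int = 1,
                       sigma_block = 0.1,
                       library_size = 1e6,
                       n_sites_per_gene = 1L,
                       site_coverage = 60,
                       allele_shape = 6,
                       allele_kappa = 100,
                       r_plastic = 0.2,
                       r_nonplastic = 0.1,
                       allelic_bias = 1,
                       snp_diff_frac_de = 0.4,
                       snp_diff_frac_null = 0.15,
                       align_frac = 0.9,
                       seed = 20160923L) {
  cfg <- as.list(environment())
  if (frac_counter + frac_increased + frac_decreased > 1) {
    stop("gene class fractions sum to more than 1")
  }
  stopifnot(dispersion >= 0, sigma_block >= 0,
            r_plastic >= 0, r_plastic <= 1,
            r_nonplastic >= 0, r_nonplastic <= 1,
            n_genes >= 1, library_size > 0)
  class(cfg) <- "sim_config"
  cfg
}

## Expected log2 offset of each (gene class, population group, diet) cell,
## relative to the gene's baseline.  Groups are the 7 population lineages.
class_offsets <- function(class, pol, cfg) {
  off <- matrix(0, nrow = length(REGIMES_ALL), ncol = 2,
                dimnames = list(REGIMES_ALL, DIETS))
  if (class == "countergradient") {
    z <- pol
    off["GA", ] <- c(z * cfg$delta_diet / 2, -z * cfg$delta_diet / 2)
    ## history: Cad lower by z*delta_hist relative to Salt, symmetric about 0
    off["Cad", ] <- off["Cad", ] - z * cfg$delta_hist / 2
    off["AC", ] <- off["AC", ] - z * cfg$delta_hist / 2
    off["Salt", ] <- off["Salt", ] + z * cfg$delta_hist / 2 +
      c(z * cfg$delta_diet / 2, -z * cfg$delta_diet / 2)
    off["AS", ] <- off["AS", ] + z * cfg$delta_hist / 2 +
      c(z * cfg$delta_diet / 2, -z * cfg$delta_diet / 2)
  } else if (class == "increased") {
    y <- pol
    d <- cfg$delta_int
    off["AC", ] <- y * d / 2
    off["Cad", ] <- y * d / 2
    off["AS", ] <- -y * d / 2
    off["Salt", ] <- -y * d / 2
    off["Temp", ] <- c(y * d / 2, -y * d / 2)
    off["Spatial", ] <- c(y * d / 2, -y * d / 2)
    ## GA left at baseline in both diets
  } else if (class == "decreased") {
    s <- pol
    m <- cfg$delta_diet
    off["AC", "salt"] <- s * m      # perturbed in foreign diet
    off["AS", "cadmium"] <- s * m
    off["Cad", "salt"] <- s * m
    off["Salt", "cadmium"] <- s * m
    off["GA", ] <- s * m / 2        # naive: intermediate in both diets
    ## Temp/Spatial adapted in both diets: 0
  }
  off
}

#' Generate a synthetic experiment
#'
#' Draws a full synthetic data set under the canonical design: a count
#' matrix, the design table, a per-site allele-count table, a
#' SNP-differentiation table and the ground-truth labels.  Counts for gene g
#' in sample s are negative binomial with mean
#' `L_s * 2^eta_gs / sum_g 2^eta_gs`, where `eta` is the gene's baseline
#' plus its class's regime/diet offsets plus a per-gene block effect.
#'
#' @param cfg a [sim_config()].
#' @return List with `counts`, `design`, `alleles`, `snp`, `truth`.  `truth`
#'   has elements `genes` (per-gene class, polarity, per-lineage expected
#'   log2 expression in each diet, Salt-regime plasticity flag and planted
#'   allelic bias) and `sites` (per-site planted log-odds bias).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- canonical_design()
  set.seed(cfg$seed)
  ## independent sub-streams so adding sites never perturbs the counts
  stream <- sample.int(.Machine$integer.max - 1L, 3L)

  n <- cfg$n_genes
  n_cls <- c(
    countergradient = round(cfg$frac_counter * n),
    increased = round(cfg$frac_increased * n),
    decreased = round(cfg$frac_decreased * n)
  )
  if (sum(n_cls) > n) stop("infeasible class fractions for this n_genes")
  classes <- rep(c(names(n_cls), "neutral"), c(n_cls, n - sum(n_cls)))
  gene_ids <- sprintf("g%04d", seq_len(n))

  ## --- counts stream ---------------------------------------------------
  set.seed(stream[1])
  baseline <- stats::rnorm(n, cfg$baseline_meanlog2, cfg$baseline_sdlog2)
  polarity <- ifelse(stats::runif(n) < 0.5, 1, -1)
  polarity[classes == "neutral"] <- 0
  blockeff <- matrix(stats::rnorm(n * 6, 0, cfg$sigma_block), nrow = n)

  ## expected log2 expression per gene for each lineage x diet cell
  eta_cell <- array(0, dim = c(n, length(REGIMES_ALL), 2),
                    dimnames = list(gene_ids, REGIMES_ALL, DIETS))
  for (g in seq_len(n)) {
    off <- if (classes[g] == "neutral") {
      matrix(0, length(REGIMES_ALL), 2, dimnames = list(REGIMES_ALL, DIETS))
    } else {
      class_offsets(classes[g], polarity[g], cfg)
    }
    eta_cell[g, , ] <- baseline[g] + off
  }

  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    eta <- eta_cell[, design$regime[j], design$diet[j]] + blockeff[, design$block[j]]
    mu <- cfg$library_size * 2^eta / sum(2^eta)
    ## dispersion 0 is the noise-free mode: counts equal their expectation
    ## (rounded), handy for exact identity checks
    counts[, j] <- if (cfg$dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    } else {
      as.integer(round(mu))
    }
  }
  storage.mode(counts) <- "integer"

  ## diet-plasticity status in the Salt regime drives allelic-bias planting
  plastic_salt <- abs(eta_cell[, "Salt", "cadmium"] - eta_cell[, "Salt", "salt"]) > 1e-9

  ## --- allele stream ----------------------------------------------------
  set.seed(stream[2])
  prev <- ifelse(plastic_salt, cfg$r_plastic, cfg$r_nonplastic)
  biased <- stats::runif(n) < prev
  pops <- unique(design$population_id)
  n_sites <- cfg$n_sites_per_gene
  site_rows <- vector("list", n)
  site_truth <- vector("list", n)
  for (g in seq_len(n)) {
    p_gene <- stats::rbeta(n_sites, cfg$allele_shape, cfg$allele_shape)
    pos <- sort(sample.int(5000L, n_sites))
    bias <- ifelse(rep(biased[g], n_sites), cfg$allelic_bias, 0)
    per_site <- vector("list", n_sites)
    for (k in seq_len(n_sites)) {
      p_pop <- stats::rbeta(length(pops),
                            p_gene[k] * cfg$allele_kappa,
                            (1 - p_gene[k]) * cfg$allele_kappa)
      names(p_pop) <- pops
      cov <- stats::rpois(nrow(design), cfg$site_coverage)
      shift <- ifelse(design$diet == "cadmium", bias[k] / 2, -bias[k] / 2)
      p_expr <- stats::plogis(stats::qlogis(p_pop[design$population_id]) + shift)
      a <- stats::rbinom(nrow(design), cov, p_expr)
      per_site[[k]] <- data.frame(
        gene_id = gene_ids[g],
        site_id = sprintf("%s_s%d", gene_ids[g], k),
        position = pos[k],
        sample_id = design$sample_id,
        a_count = a,
        b_count = cov - a,
        stringsAsFactors = FALSE
      )
    }
    site_rows[[g]] <- do.call(rbind, per_site)
    site_truth[[g]] <- data.frame(
      gene_id = gene_ids[g],
      site_id = sprintf("%s_s%d", gene_ids[g], seq_len(n_sites)),
      bias = bias,
      stringsAsFactors = FALSE
    )
  }
  alleles <- do.call(rbind, site_rows)
  rownames(alleles) <- NULL

  ## --- SNP stream -------------------------------------------------------
  set.seed(stream[3])
  has_hist <- classes == "countergradient"
  p_diff <- ifelse(has_hist, cfg$snp_diff_frac_de, cfg$snp_diff_frac_null)
  snp_list <- vector("list", n)
  for (g in seq_len(n)) {
    regions <- sample(SNP_REGIONS, sample(1:3, 1))
    diffed <- stats::runif(length(regions)) < p_diff[g]
    q <- ifelse(diffed, 10^stats::runif(length(regions), -8, -4),
                stats::runif(length(regions), 0.01, 1))
    if (biased[g]) {
      dir_aligned <- stats::runif(length(regions)) < cfg$align_frac
      direction <- ifelse(dir_aligned, 1L, -1L)
    } else {
      direction <- sample(c(-1L, 1L), length(regions), replace = TRUE)
    }
    snp_list[[g]] <- data.frame(
      snp_id = sprintf("%s_snp%d", gene_ids[g], seq_along(regions)),
      gene_id = gene_ids[g],
      region = regions,
      diff_q = q,
      direction = direction,
      stringsAsFactors = FALSE
    )
  }
  snp <- do.call(rbind, snp_list)
  rownames(snp) <- NULL

  norm_cols <- do.call(rbind, lapply(REGIMES_ALL, function(r) {
    data.frame(lineage = r, diet = DIETS,
               col = paste("eta", r, DIETS, sep = "_"),
               stringsAsFactors = FALSE)
  }))
  genes_truth <- data.frame(
    gene_id = gene_ids, class = classes, polarity = polarity,
    plastic_salt = plastic_salt, allelic_bias = ifelse(biased, cfg$allelic_bias, 0),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(norm_cols))) {
    genes_truth[[norm_cols$col[i]]] <- eta_cell[, norm_cols$lineage[i], norm_cols$diet[i]]
  }

  list(
    counts = counts,
    design = design,
    alleles = alleles,
    snp = snp,
    truth = list(genes = genes_truth,
                 sites = do.call(rbind, site_truth))
  )
}

#' Summarize ground-truth labels
#'
#' @param truth the `truth` element of [simulate_experiment()] output.
#' @return List with `class_counts` (named integer vector summing to the
#'   number of genes), `n_biased_sites` (sites with planted allelic bias) and
#'   `mean_abs_hist` (mean planted |Cad-vs-Salt| history effect among
#'   countergradient genes, log2 scale).
#' @export
summarize_truth <- function(truth) {
  g <- truth$genes
  cls <- factor(g$class, levels = c("countergradient", "increased", "decreased", "neutral"))
  hist_eff <- (g$eta_Cad_cadmium + g$eta_Cad_salt) / 2 -
    (g$eta_Salt_cadmium + g$eta_Salt_salt) / 2
  cg <- g$class == "countergradient"
  list(
    class_counts = table(cls),
    n_biased_sites = sum(truth$sites$bias != 0),
    mean_abs_hist = if (any(cg)) mean(abs(hist_eff[cg])) else NA_real_
  )
}
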