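#' Pipeline configuration
#'
#' All thresholds of the analysis stages with their defaults, plus the
#' global seed.  A YAML file with any subset of these names can be loaded
#' with [read_pipeline_config()].
#'
#' @param ga_log2fc_thr ancestral-plasticity screen |log2FC| cutoff.
#' @param hist_q_thr selection-history FDR cutoff.
#' @param opt_diff_thr increased-plasticity screen optimal-pair cutoff.
#' @param on_diff_thr decreased-plasticity screen Optimal-vs-Non-adapted
#'   cutoff.
#' @param ratio plasticity-to-divergence ratio for both ancestor screens.
#' @param increased_screen_reference reference divergence for the increased
#'   screen (`"optimal_pair"` or `"within_diet"`).
#' @param allelic_p_thr CMH significance threshold.
#' @param abund_p_thr abundance-plasticity p threshold.
#' @param div_thr site diversity (2pq) threshold.
#' @param n_thr site total-count threshold.
#' @param n_perm permutation count for the enrichment null.
#' @param diff_q_thr SNP differentiation q threshold.
#' @param n_boot bootstrap replicates for direction alignment.
#' @param allelic_regimes regimes to run the allelic scan on.
#' @param seed global integer seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(ga_log2fc_thr = 0.4,
                            hist_q_thr = 0.1,
                            opt_diff_thr = 0.4,
                            on_diff_thr = 0.3,
                            ratio = 0.5,
                            increased_screen_reference = "optimal_pair",
                            allelic_p_thr = 0.01,
                            abund_p_thr = 0.05,
                            div_thr = 0.20,
                            n_thr = 100,
                            n_perm = 5000L,
                            diff_q_thr = 0.001,
                            n_boot = 2000L,
                            allelic_regimes = REGIMES_EVOLVED,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   argument names.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a data set (typically [simulate_experiment()]
#' output or [read_tables()] input): block-wise count down-sampling,
#' normalization, the differential-expression fits, the countergradient
#' analysis, both ancestor-based plasticity screens with their scores and
#' regime comparisons, the adaptive-distance summaries, and — when an
#' allele table is present — the allelic-plasticity scan with the
#' permutation-enrichment null, plus the SNP-region enrichment and
#' direction-alignment analyses when a SNP table is present.  Missing
#' optional tables disable the dependent stages with a warning.  All
#' randomness derives from `cfg$seed`; outputs written by `out_dir` are
#' byte-identical across runs with the same data and config.
#'
#' @param data list with `counts`, `design` and optionally `alleles`,
#'   `snp` (see [read_tables()]).
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV plus a JSON run manifest.
#' @return List with the per-stage results (`de`, `countergradient`,
#'   `screens`, `scores`, `phi`, `allelic`, `snp_enrichment`, `manifest`).
#' @export
run_pipeline <- function(data, cfg = pipeline_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) message(sprintf("[hetevo +%.1fs] %s",
                                         proc.time()[["elapsed"]] - t0, msg))
  design <- data$design
  issues <- validate_design(design)
  if (length(issues)) {
    stop(sprintf("invalid design: %s", paste(issues, collapse = "; ")))
  }

  stage("down-sampling counts within blocks")
  counts <- downsample_counts(data$counts, design, seed = cfg$seed)
  expr <- normalize_expression(counts)

  stage("fitting expression models")
  de_hist <- fit_gene_models(expr, design, "two_regimes_both_diets",
                             regimes = c("Cad", "Salt"), counts = counts)
  de_diet <- lapply(stats::setNames(nm = cfg$allelic_regimes), function(rg) {
    fit_gene_models(expr, design, "one_regime_diet_effect", regime = rg,
                    counts = counts)
  })

  stage("countergradient analysis")
  cg <- countergradient_analysis(expr, design, de_hist,
                                 ga_threshold = cfg$ga_log2fc_thr,
                                 q_threshold = cfg$hist_q_thr)

  stage("plasticity screens and scores")
  set_inc <- screen_increased(expr, design, opt_diff_thr = cfg$opt_diff_thr,
                              ratio = cfg$ratio,
                              reference = cfg$increased_screen_reference)
  set_dec <- screen_decreased(expr, design, on_diff_thr = cfg$on_diff_thr,
                              ratio = cfg$ratio)
  scores_inc <- polarized_plasticity_score(expr, design, set_inc)
  scores_dec <- absolute_plasticity_score(expr, design, set_dec)
  comp_inc <- regime_anova_tukey(scores_inc)
  comp_dec <- regime_anova_tukey(scores_dec)
  het_inc <- heterogeneity_test(scores_inc)
  phi_inc <- adaptive_distance(expr, design, set_inc)
  phi_dec <- adaptive_distance(expr, design, set_dec)

  allelic <- NULL
  if (!is.null(data$alleles)) {
    stage("allelic-plasticity scan")
    alleles_ds <- downsample_sites(data$alleles, design, seed = cfg$seed)
    allelic <- lapply(stats::setNames(nm = cfg$allelic_regimes), function(rg) {
      scan <- allelic_scan(alleles_ds, design, rg, p_thr = cfg$allelic_p_thr,
                           div_thr = cfg$div_thr, n_thr = cfg$n_thr)
      enr <- tryCatch(
        permutation_null(scan, de_diet[[rg]], abund_p_thr = cfg$abund_p_thr,
                         n_perm = cfg$n_perm, seed = cfg$seed),
        error = function(e) {
          warning(sprintf("enrichment skipped for %s: %s", rg, conditionMessage(e)))
          NULL
        })
      align <- NULL
      if (!is.null(data$snp)) {
        align <- tryCatch(
          direction_alignment(scan, data$snp, diff_q_thr = cfg$diff_q_thr,
                              n_boot = cfg$n_boot, seed = cfg$seed),
          error = function(e) {
            warning(sprintf("direction alignment skipped for %s: %s",
                            rg, conditionMessage(e)))
            NULL
          })
      }
      list(scan = scan, enrichment = enr, alignment = align)
    })
  } else {
    warning("no allele table supplied; allelic stages skipped")
  }

  snp_enr <- NULL
  if (!is.null(data$snp)) {
    stage("SNP-region enrichment")
    universe <- de_hist$gene_id[de_hist$tested]
    hist_set <- screen_history_genes(de_hist, q_threshold = cfg$hist_q_thr)
    snp_enr <- tryCatch(
      snp_region_enrichment(hist_set, data$snp, universe,
                            diff_q_thr = cfg$diff_q_thr),
      error = function(e) {
        warning(sprintf("SNP-region enrichment skipped: %s", conditionMessage(e)))
        NULL
      })
  } else {
    warning("no SNP table supplied; SNP stages skipped")
  }

  manifest <- list(
    package = "hetevo",
    version = as.character(utils::packageVersion("hetevo")),
    config = cfg[setdiff(names(cfg), "allelic_regimes")],
    allelic_regimes = cfg$allelic_regimes,
    epsilon = expr$epsilon,
    de_engine = "OLS on log2(E + epsilon); fixed-effect design, partial F-tests",
    heterogeneity_block = "fixed effect",
    n_genes = nrow(counts),
    n_samples = ncol(counts)
  )

  out <- list(
    counts_downsampled = counts, expr = expr,
    de = list(history = de_hist, diet = de_diet),
    countergradient = cg,
    screens = list(increased = set_inc, decreased = set_dec),
    scores = list(increased = scores_inc, decreased = scores_dec,
                  anova_increased = comp_inc, anova_decreased = comp_dec,
                  heterogeneity_increased = het_inc),
    phi = list(increased = phi_inc, decreased = phi_dec),
    allelic = allelic,
    snp_enrichment = snp_enr,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

## Serialize the main stage outputs as TSV + JSON (deterministic formatting).
write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tsv_plain(res$de$history, file.path(out_dir, "de_history.tsv"))
  write_tsv_plain(res$countergradient$overlap,
                  file.path(out_dir, "countergradient_genes.tsv"))
  write_tsv_plain(
    data.frame(block = names(res$countergradient$divergence$block_means),
               mean_polarized_divergence = res$countergradient$divergence$block_means),
    file.path(out_dir, "countergradient_block_means.tsv"))
  write_json_stable(
    c(res$countergradient$sign_test,
      list(n_opposing = res$countergradient$n_opposing,
           n_total = res$countergradient$n_total),
      t_test = list(res$countergradient$block_test)),
    file.path(out_dir, "countergradient_tests.json"))
  write_tsv_plain(res$screens$increased, file.path(out_dir, "screen_increased.tsv"))
  write_tsv_plain(res$screens$decreased, file.path(out_dir, "screen_decreased.tsv"))
  write_tsv_plain(res$scores$increased, file.path(out_dir, "scores_increased.tsv"))
  write_tsv_plain(res$scores$decreased, file.path(out_dir, "scores_decreased.tsv"))
  write_tsv_plain(res$phi$increased$phi_bar, file.path(out_dir, "phi_increased.tsv"))
  write_tsv_plain(res$phi$decreased$phi_bar, file.path(out_dir, "phi_decreased.tsv"))
  if (!is.null(res$allelic)) {
    for (rg in names(res$allelic)) {
      write_tsv_plain(res$allelic[[rg]]$scan$result,
                      file.path(out_dir, sprintf("allelic_%s.tsv", rg)))
      if (!is.null(res$allelic[[rg]]$enrichment)) {
        enr <- res$allelic[[rg]]$enrichment
        write_json_stable(enr[c("f1", "f2", "diff_f_observed", "p_perm",
                                "n_perm", "n_demoted")],
                          file.path(out_dir, sprintf("enrichment_%s.json", rg)))
      }
      if (!is.null(res$allelic[[rg]]$alignment)) {
        al <- res$allelic[[rg]]$alignment
        write_json_stable(list(mean_sign = al$mean_sign, ci_low = al$ci[1],
                               ci_high = al$ci[2],
                               excludes_zero = al$excludes_zero,
                               n_genes = al$n_genes, n_boot = al$n_boot),
                          file.path(out_dir, sprintf("alignment_%s.json", rg)))
      }
    }
  }
  if (!is.null(res$snp_enrichment)) {
    write_tsv_plain(res$snp_enrichment, file.path(out_dir, "snp_region_enrichment.tsv"))
  }
  write_json_stable(res$manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
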