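#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for the experimental design.
REGIMES_EVOLVED <- c("Cad", "Salt", "Temp", "Spatial")
REGIMES_ANCESTOR <- c("GA", "AC", "AS")
REGIMES_ALL <- c(REGIMES_ANCESTOR, REGIMES_EVOLVED)
DIETS <- c("cadmium", "salt")
SNP_REGIONS <- c("exon", "intron", "flank1kb")

DESIGN_COLS <- c("sample_id", "population_id", "regime", "replicate", "diet", "block")
ALLELE_COLS <- c("gene_id", "site_id", "position", "sample_id", "a_count", "b_count")
SNP_COLS <- c("snp_id", "gene_id", "region", "diff_q", "direction")

#' Canonical experimental design
#'
#' Builds the full 46-sample layout of the selection experiment: four evolved
#' regimes (constant cadmium `Cad`, constant salt `Salt`, temporally varying
#' `Temp`, spatially varying `Spatial`), each with five replicate populations,
#' every population assayed in both larval diets.  Replicate `r` of every
#' regime is assayed in experimental block `r` (blocks 1-5, eight samples per
#' block).  The three ancestors (`GA`, the naive grand ancestor; `AC`, the
#' cadmium-adapted ancestor; `AS`, the salt-adapted ancestor) are assayed in
#' both diets in block 6.
#'
#' @return A `data.frame` with columns `sample_id`, `population_id`,
#'   `regime`, `replicate` (0 for ancestors), `diet` and `block`.
#' @examples
#' d <- canonical_design()
#' table(d$regime, d$diet)
#' @export
canonical_design <- function() {
  evolved <- expand.grid(
    diet = DIETS, regime = REGIMES_EVOLVED, replicate = 1:5,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  evolved$population_id <- paste0(evolved$regime, evolved$replicate)
  evolved$block <- evolved$replicate
  anc <- expand.grid(
    diet = DIETS, regime = REGIMES_ANCESTOR,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  anc$replicate <- 0L
  anc$population_id <- anc$regime
  anc$block <- 6L
  d <- rbind(
    evolved[, c("population_id", "regime", "replicate", "diet", "block")],
    anc[, c("population_id", "regime", "replicate", "diet", "block")]
  )
  d$sample_id <- paste(d$population_id, d$diet, sep = "_")
  d$replicate <- as.integer(d$replicate)
  d$block <- as.integer(d$block)
  rownames(d) <- NULL
  d[, DESIGN_COLS]
}

#' Validate a design table
#'
#' Checks the invariants of the experimental layout and reports every
#' violation rather than stopping at the first: required columns and
#' controlled vocabularies; uniqueness of `sample_id` and of each
#' `(population_id, diet)` pair; five replicate populations per evolved
#' regime; eight samples per experimental block (one replicate of each of the
#' four evolved regimes in each diet); six ancestor samples (GA, AC, AS in
#' both diets) in the ancestor block.
#'
#' @param design design `data.frame` (see [canonical_design()]).
#' @param ancestor_block block number holding the ancestors (default 6).
#' @return Character vector of violation messages; `character(0)` iff the
#'   design is a complete balanced layout.
#' @export
validate_design <- function(design, ancestor_block = 6L) {
  report <- character(0)
  missing_cols <- setdiff(DESIGN_COLS, names(design))
  if (length(missing_cols)) {
    return(sprintf("missing design column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  bad_regime <- setdiff(unique(design$regime), REGIMES_ALL)
  if (length(bad_regime)) {
    report <- c(report, sprintf("unknown regime(s): %s", paste(bad_regime, collapse = ", ")))
  }
  bad_diet <- setdiff(unique(design$diet), DIETS)
  if (length(bad_diet)) {
    report <- c(report, sprintf("unknown diet(s): %s", paste(bad_diet, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    report <- c(report, "duplicated sample_id")
  }
  key <- paste(design$population_id, design$diet)
  if (anyDuplicated(key)) {
    report <- c(report, sprintf(
      "duplicated (population_id, diet) pair(s): %s",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    ))
  }
  for (rg in REGIMES_EVOLVED) {
    n_pop <- length(unique(design$population_id[design$regime == rg]))
    if (n_pop != 5L) {
      report <- c(report, sprintf("regime %s has %d replicate populations (expected 5)", rg, n_pop))
    }
  }
  ## each population must appear in both diets
  for (pop in unique(design$population_id)) {
    have <- sort(unique(design$diet[design$population_id == pop]))
    if (!identical(have, sort(DIETS))) {
      report <- c(report, sprintf("population %s lacks diet(s): %s",
                                  pop, paste(setdiff(DIETS, have), collapse = ", ")))
    }
  }
  ## block composition
  exp_blocks <- sort(unique(design$block[design$regime %in% REGIMES_EVOLVED]))
  for (b in exp_blocks) {
    sub <- design[design$block == b & design$regime %in% REGIMES_EVOLVED, ]
    cells <- expand.grid(regime = REGIMES_EVOLVED, diet = DIETS, stringsAsFactors = FALSE)
    have <- paste(sub$regime, sub$diet)
    miss <- cells[!paste(cells$regime, cells$diet) %in% have, ]
    if (nrow(miss)) {
      report <- c(report, sprintf(
        "block %d missing cell(s): %s", b,
        paste(paste(miss$regime, miss$diet, sep = "/"), collapse = ", ")
      ))
    }
    if (nrow(sub) != 8L) {
      report <- c(report, sprintf("block %d has %d experimental samples (expected 8)", b, nrow(sub)))
    }
  }
  anc <- design[design$regime %in% REGIMES_ANCESTOR, ]
  if (nrow(anc)) {
    if (!all(anc$block == ancestor_block)) {
      report <- c(report, sprintf("ancestor samples outside block %d", ancestor_block))
    }
    cells <- expand.grid(regime = REGIMES_ANCESTOR, diet = DIETS, stringsAsFactors = FALSE)
    have <- paste(anc$regime, anc$diet)
    miss <- cells[!paste(cells$regime, cells$diet) %in% have, ]
    if (nrow(miss)) {
      report <- c(report, sprintf(
        "ancestor block missing cell(s): %s",
        paste(paste(miss$regime, miss$diet, sep = "/"), collapse = ", ")
      ))
    }
  } else {
    report <- c(report, "no ancestor samples present")
  }
  report
}

#' Check a count matrix against a design
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param design design table whose `sample_id` must cover every column.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_counts <- function(counts, design) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated gene_id in counts")
  if (any(counts < 0)) stop("negative count")
  if (any(counts != round(counts))) stop("non-integer count")
  extra <- setdiff(colnames(counts), design$sample_id)
  if (length(extra)) {
    stop(sprintf("sample(s) in counts absent from design: %s", paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}

validate_alleles <- function(alleles, design) {
  missing_cols <- setdiff(ALLELE_COLS, names(alleles))
  if (length(missing_cols)) {
    stop(sprintf("allele table missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(alleles) == 0) return(invisible(TRUE))
  if (any(alleles$a_count < 0) || any(alleles$b_count < 0)) stop("negative allele count")
  if (any(alleles$a_count != round(alleles$a_count)) ||
      any(alleles$b_count != round(alleles$b_count))) stop("non-integer allele count")
  key <- paste(alleles$gene_id, alleles$site_id, alleles$sample_id)
  if (anyDuplicated(key)) stop("duplicated (gene_id, site_id, sample_id) in allele table")
  extra <- setdiff(unique(alleles$sample_id), design$sample_id)
  if (length(extra)) {
    stop(sprintf("sample(s) in allele table absent from design: %s", paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}

validate_snp <- function(snp) {
  missing_cols <- setdiff(SNP_COLS, names(snp))
  if (length(missing_cols)) {
    stop(sprintf("SNP table missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(snp) == 0) return(invisible(TRUE))
  if (any(snp$diff_q < 0 | snp$diff_q > 1)) stop("diff_q outside [0, 1]")
  bad <- setdiff(unique(snp$region), SNP_REGIONS)
  if (length(bad)) stop(sprintf("unknown SNP region(s): %s", paste(bad, collapse = ", ")))
  if (!all(snp$direction %in% c(-1, 1))) stop("direction must be -1 or +1")
  invisible(TRUE)
}

read_tsv_strict <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  x <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", what, paste(missing_cols, collapse = ", ")))
  }
  x
}

#' Read the pipeline input tables
#'
#' Reads the gene-level count matrix, the sample design table and,
#' optionally, the per-site allele-count table and the genomic
#' SNP-differentiation table, all as tab-separated files with a header row.
#' All type invariants are checked on read; row and column order are
#' preserved as found in the files.
#'
#' @param counts_path TSV with a `gene_id` column followed by one integer
#'   column per sample.
#' @param design_path TSV with columns `sample_id`, `population_id`,
#'   `regime`, `replicate`, `diet`, `block`.
#' @param allele_path optional TSV with columns `gene_id`, `site_id`,
#'   `position`, `sample_id`, `a_count`, `b_count` (long format; one row per
#'   site per sample).
#' @param snp_path optional TSV with columns `snp_id`, `gene_id`, `region`,
#'   `diff_q`, `direction`.
#' @return A list with elements `counts` (integer matrix), `design`
#'   (data.frame), `alleles` (data.frame or `NULL`), `snp` (data.frame or
#'   `NULL`).
#' @export
read_tables <- function(counts_path, design_path, allele_path = NULL, snp_path = NULL) {
  design <- read_tsv_strict(design_path, DESIGN_COLS, "design")
  design$replicate <- as.integer(design$replicate)
  design$block <- as.integer(design$block)
  key <- paste(design$population_id, design$diet)
  if (anyDuplicated(key)) {
    stop(sprintf("design: duplicated (population_id, diet) pair: %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }

  cm <- read_tsv_strict(counts_path, "gene_id", "counts")
  gene_ids <- as.character(cm$gene_id)
  counts <- as.matrix(cm[, setdiff(names(cm), "gene_id"), drop = FALSE])
  bad <- which(abs(counts - round(counts)) > 0 | is.na(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("counts: non-integer or missing value at row %d", bad[1, 1]))
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_ids
  validate_counts(counts, design)

  alleles <- NULL
  if (!is.null(allele_path)) {
    alleles <- read_tsv_strict(allele_path, ALLELE_COLS, "allele table")
    alleles$position <- as.integer(alleles$position)
    alleles$a_count <- as.integer(alleles$a_count)
    alleles$b_count <- as.integer(alleles$b_count)
    validate_alleles(alleles, design)
  }
  snp <- NULL
  if (!is.null(snp_path)) {
    snp <- read_tsv_strict(snp_path, SNP_COLS, "SNP table")
    snp$direction <- as.integer(snp$direction)
    validate_snp(snp)
  }
  list(counts = counts, design = design, alleles = alleles, snp = snp)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(format(x, digits = 12, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write the pipeline tables as TSV
#'
#' Inverse of [read_tables()]: writes each supplied object as a
#' tab-separated file that `read_tables()` re-parses to an equal object
#' (exact for integers, >= 10 significant digits for reals).
#'
#' @param tables list as returned by [read_tables()] or
#'   [simulate_experiment()] (elements `counts`, `design`, optionally
#'   `alleles`, `snp`; other elements are ignored).
#' @param out_dir output directory, created if needed.
#' @return Named character vector of written paths.
#' @export
write_tables <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir))
  paths <- c()
  if (!is.null(tables$counts)) {
    cm <- data.frame(gene_id = rownames(tables$counts),
                     tables$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    paths["counts"] <- write_tsv_plain(cm, file.path(out_dir, "counts.tsv"))
  }
  if (!is.null(tables$design)) {
    paths["design"] <- write_tsv_plain(tables$design[, DESIGN_COLS],
                                       file.path(out_dir, "design.tsv"))
  }
  if (!is.null(tables$alleles)) {
    paths["alleles"] <- write_tsv_plain(tables$alleles[, ALLELE_COLS, drop = FALSE],
                                        file.path(out_dir, "alleles.tsv"))
  }
  if (!is.null(tables$snp)) {
    paths["snp"] <- write_tsv_plain(tables$snp[, SNP_COLS, drop = FALSE],
                                    file.path(out_dir, "snp.tsv"))
  }
  paths
}

## Sample lookup helpers used throughout the pipeline.
sample_of <- function(design, population_id, diet) {
  s <- design$sample_id[design$population_id == population_id & design$diet == diet]
  if (length(s) != 1L) {
    stop(sprintf("expected exactly one sample for population %s in diet %s, found %d",
                 population_id, diet, length(s)))
  }
  s
}

populations_of <- function(design, regimes) {
  unique(design$population_id[design$regime %in% regimes])
}
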