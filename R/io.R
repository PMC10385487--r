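## File interchange: genotype matrices (CSV and VCF), cross plans, plot
## tables, and a convenience wrapper running the full analysis pipeline on
## in-memory objects.

#' Read a genotype dosage matrix
#'
#' CSV input is a matrix with line IDs in the first column and SNP IDs in
#' the header; VCF input (extension `.vcf` or `.vcf.gz`) is parsed with the
#' vcfR package, dosage being the count of alternate alleles in the GT
#' field. Non-biallelic VCF records are skipped with a warning; missing
#' calls are preserved as `NA`.
#'
#' @param path Path to a CSV or VCF file.
#' @return Numeric dosage matrix (lines x SNPs).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
      nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
    if (!all(biallelic))
      warning(sum(!biallelic), " non-biallelic VCF record(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[biallelic, , drop = FALSE]
    dos <- apply(gt, 2, function(col) {
      a <- strsplit(gsub("\\|", "/", col), "/", fixed = TRUE)
      vapply(a, function(x) {
        if (length(x) == 0L || anyNA(x) || any(x == "."))
          return(NA_real_)
        sum(x == "1")
      }, 0)
    })
    dos <- t(dos)
    colnames(dos) <- rownames(gt)
    return(dos)
  }
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed genotype CSV: non-numeric dosages")
  if (any(!is.na(m) & !(m %in% c(0, 0.5, 1, 1.5, 2))))
    stop("dosages outside [0, 2] genotype classes in ", path)
  rownames(m) <- ids
  m
}

#' Write a genotype dosage matrix as CSV
#'
#' @param g Dosage matrix.
#' @param path Output path.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(line = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Write integer dosages as a minimal VCF
#'
#' Emits one biallelic SNP record per column with unphased GT calls
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.).
#'
#' @param g Dosage matrix with values 0/1/2 or NA.
#' @param path Output path.
#' @param chrom Chromosome label(s), recycled across SNPs.
#' @export
write_genotypes_vcf <- function(g, path, chrom = "1") {
  samples <- rownames(g)
  snps <- colnames(g)
  chrom <- rep_len(chrom, ncol(g))
  gtmap <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (j in seq_len(ncol(g))) {
    calls <- gtmap[as.character(g[, j])]
    calls[is.na(calls)] <- "./."
    writeLines(paste(c(chrom[j], j, snps[j], "A", "T", ".", "PASS", ".",
                       "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cross plan
#'
#' @param path CSV with columns `hybrid_id`, `parent1`, `parent2`,
#'   `nursery` and optionally `shared`.
#' @return Validated `crossplan` data frame.
#' @export
read_crossplan <- function(path) {
  cp <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hybrid_id", "parent1", "parent2", "nursery")
  miss <- setdiff(need, names(cp))
  if (length(miss)) stop("cross plan missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cp$hybrid_id)) stop("duplicated hybrid IDs in cross plan")
  if (any(cp$parent1 == cp$parent2)) stop("self-crosses in cross plan")
  if (is.null(cp$shared)) cp$shared <- FALSE
  class(cp) <- c("crossplan", "data.frame")
  cp
}

#' Read a plot-level phenotype table
#'
#' @param path CSV with columns `trial`, `row`, `col`, `block`, `hybrid_id`
#'   and one or more trait columns; `location` and `year` are optional but
#'   required for the multi-trial model.
#' @param crossplan Optional cross plan for referential-integrity checking;
#'   plots referencing unknown hybrids are an error listing the offenders.
#' @return Validated plot data frame.
#' @export
read_plots <- function(path, crossplan = NULL) {
  pl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "row", "col", "block", "hybrid_id")
  miss <- setdiff(need, names(pl))
  if (length(miss)) stop("plot table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(crossplan)) {
    orphans <- setdiff(unique(pl$hybrid_id), crossplan$hybrid_id)
    if (length(orphans))
      stop("plots reference hybrids absent from the cross plan: ",
           paste(orphans, collapse = ", "))
  }
  pl
}

#' Write a synthetic dataset to a directory
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.csv"))
  utils::write.csv(sim$crossplan, file.path(dir, "crossplan.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  truth <- sim$truth
  truth$gxt <- as.data.frame(truth$gxt)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full two-stage analysis pipeline
#'
#' Marker QC (MAF, missingness, kinship-corrected LD pruning), relationship
#' matrices, per-trial spatial models with AIC selection, the multi-trial
#' model, both combining-ability models with their variance partitions, and
#' optionally the evaluated-parent cross-validation.
#'
#' @param genotypes Parent dosage matrix.
#' @param crossplan Cross plan data frame.
#' @param plots Plot table.
#' @param trait Trait column to analyse.
#' @param maf_min,miss_max,rv2_max Marker QC thresholds.
#' @param ladder Ladder entries for stage 1 (default all eight).
#' @param n_reps Cross-validation repetitions (0 skips cross-validation).
#' @param cv_models Genetic models scored in cross-validation.
#' @param seed Seed for the cross-validation splits.
#' @param control Optimizer control.
#' @return List with the QC'd marker set, kernels, stage-1 BLUEs and model
#'   selection, the multi-trial fit and its variance ratios, both combining
#'   fits and variance partitions, and (if requested) the cross-validation
#'   results.
#' @export
run_pipeline <- function(genotypes, crossplan, plots, trait,
                         maf_min = 0.05, miss_max = 0.10, rv2_max = 0.5,
                         ladder = ladder_entries()$label,
                         n_reps = 0L, cv_models = c("GCA", "GCA+SCA"),
                         seed = 1L, control = reml_control()) {
  kept <- filter_snps(genotypes, maf_min = maf_min, miss_max = miss_max)
  g <- impute_mean(genotypes[, kept, drop = FALSE])
  k_all <- grm_vanraden(g)
  pruned <- prune_ld(g, k_all + diag(1e-6, nrow(k_all)), rv2_max = rv2_max)
  g <- g[, pruned, drop = FALSE]
  Gp <- grm_vanraden(g)
  pca <- snp_pca(g)
  have <- crossplan$parent1 %in% rownames(g) &
    crossplan$parent2 %in% rownames(g)
  cp <- crossplan[have, , drop = FALSE]
  Xh <- hybrid_dosages(g, cp)
  Gh <- grm_vanraden(Xh)
  D <- dominance_matrix(Xh)
  plots <- plots[plots$hybrid_id %in% cp$hybrid_id, , drop = FALSE]
  s1 <- stage1_blues(plots, trait, entries = ladder, control = control)
  mt <- fit_multitrial(plots, trait, control = control)
  avg <- avg_targets(mt)
  gca <- fit_gca(s1$blues, cp, Gp, Gh, control = control)
  gca_sca <- fit_gca_sca(s1$blues, cp, Gp, Gh, D, gca, control = control)
  out <- list(kept_snps = pruned, Gp = Gp, Gh = Gh, D = D, pca = pca,
              stage1 = s1, multitrial = mt, avg = avg,
              gca = gca, gca_sca = gca_sca,
              partition = rbind(partition_variance(gca),
                                partition_variance(gca_sca)),
              heritability = vapply(rownames(mt$Sigma_a), function(l)
                heritability(mt, l), 0),
              cv = coefficients_of_variation(mt))
  if (n_reps > 0L)
    out$crossval <- run_crossval(s1$blues, avg, cp, Gp, Gh, D, trait = trait,
                                 n_reps = n_reps, models = cv_models,
                                 seed = seed, control = control)
  out
}
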