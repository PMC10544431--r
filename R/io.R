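#' Write a dosage matrix as VCF v4.2
#'
#' Biallelic SNPs, unphased diploid GT field, chromosome/position/allele
#' labels taken from the SNP table. Output is plain text and byte-stable for
#' identical inputs.
#'
#' @param genotypes dosage matrix, individuals x SNPs (0/1/2, NA allowed).
#' @param freqs SNP table with `snp_id`, `chr`, `pos`, `ref`, `alt`.
#' @param path output file path (`.vcf`).
#' @export
write_cohort_vcf <- function(genotypes, freqs, path) {
  snps <- colnames(genotypes)
  idx <- match(snps, freqs$snp_id)
  if (anyNA(idx)) stop("genotype columns missing from the SNP table")
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = length(snps), ncol = nrow(genotypes))
  gmat <- t(genotypes)
  ok <- !is.na(gmat)
  gt[ok] <- gt_codes[gmat[ok] + 1L]
  body <- paste(freqs$chr[idx], freqs$pos[idx], snps, freqs$ref[idx],
                freqs$alt[idx], ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=admixMR",
              "##contig=<ID=1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Parses a biallelic-SNP VCF (via `vcfR`) and converts GT fields to
#' effect-allele (ALT) dosages.
#'
#' @param path VCF file path.
#' @return list: `genotypes` (individuals x SNPs dosage matrix) and `snps`
#'   (data.frame `snp_id`, `chr`, `pos`, `ref`, `alt`).
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = fix$ID, chr = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  list(genotypes = t(dos), snps = snps)
}

#' Write the cohort sample sheet as TSV
#'
#' Columns: sample_id, status, age, age_at_diagnosis, family_history, er, pr,
#' her2 and the true simulated ancestry proportions (one column per
#' subpopulation).
#'
#' @param cohort an `admix_cohort` with phenotypes assigned.
#' @param path output file path.
#' @export
write_samples_tsv <- function(cohort, path) {
  s <- cohort$samples[, c("sample_id", "status", "age", "age_at_diagnosis",
                          "family_history", "er", "pr", "her2")]
  q <- as.data.frame(cohort$true_q)
  names(q) <- paste0("true_q_", colnames(cohort$true_q))
  write.table(cbind(s, q), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet written by [write_samples_tsv()]
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_samples_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a PheWAS catalog TSV
#' @param catalog data.frame `snp_id`, `phenotype`, `pval`.
#' @param path file path.
#' @export
write_phewas_tsv <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phewas_tsv
#' @export
read_phewas_tsv <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("snp_id", "phenotype", "pval")
  if (!all(required %in% names(out)))
    stop("malformed catalog: need columns snp_id, phenotype, pval")
  out
}

#' Write GWAS-style summary statistics as TSV
#' @param stats a scan result carrying snp_id/alleles/eaf/beta/se/pval/n.
#' @param path file path.
#' @export
write_sumstats_tsv <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Save a simulation configuration as YAML (seeds included)
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' Write the machine-readable pipeline report (JSON)
#'
#' Serialises stage counts, thresholds, seeds, ancestry summaries and the
#' per-method estimate table for provenance.
#'
#' @param report an `mr_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  payload <- list(stage_counts = as.list(report$stage_counts),
                  thresholds = report$pconfig[c("gwas_p", "phewas_p", "ld_r2",
                                                "radial_p", "top_k")],
                  seeds = list(simulation = report$seed,
                               weighted_median = report$pconfig$wm_seed),
                  ancestry_controls = as.list(report$ancestry_controls),
                  estimates = mr_report_table(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
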