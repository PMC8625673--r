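#' Read a genotype table from dosage TSV or VCF
#'
#' Reads subjects-by-SNPs minor-allele dosages either from a tab-delimited
#' dosage matrix (first column `subject_id`, one integer column per SNP,
#' empty/NA = missing) or from a VCF v4.2 file with GT genotype fields
#' (`0/0`, `0/1`, `1/1`, phased `|` accepted, `./.` = missing).
#'
#' Dosages are re-expressed as counts of the *minor* allele as observed in
#' the data: any SNP whose coded allele has frequency above 0.5 is flipped
#' (`dosage <- 2 - dosage`) and flagged, so downstream MAF-based rules never
#' depend on file allele order. Exact ties (frequency 0.5) keep the file
#' coding.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A list with `genotypes` (tibble: `subject_id` + one dosage column
#'   per SNP) and `snp_info` (tibble: `snp_id`, `gene` when available,
#'   `flipped`).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("genotype file '%s' not found.", path),
          class = "aldaphen_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  parsed <- if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
  recode_to_minor(parsed)
}

read_genotypes_tsv <- function(path) {
  geno <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(geno)) {
    abort("dosage TSV must have a `subject_id` first column.",
          class = "aldaphen_parse_error")
  }
  snps <- setdiff(names(geno), "subject_id")
  for (s in snps) {
    v <- geno[[s]]
    bad <- which(!is.na(v) & !(v %in% 0:2))
    if (length(bad)) {
      abort(sprintf("invalid dosage '%s' for SNP %s at line %d of %s.",
                    v[bad[1]], s, bad[1] + 1L, path),
            class = "aldaphen_parse_error")
    }
    geno[[s]] <- as.integer(v)
  }
  list(genotypes = geno,
       snp_info = tibble(snp_id = snps, gene = NA_character_))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  dosage_of <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    bad <- which(!is.na(g) & !g %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
    if (length(bad)) {
      abort(sprintf("unsupported GT value '%s' in %s.", g[bad[1]], path),
            class = "aldaphen_parse_error")
    }
    out
  }
  mat <- apply(gt, 1, dosage_of)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = ncol(gt))
  colnames(mat) <- fix$ID
  geno <- dplyr::bind_cols(tibble(subject_id = colnames(gt)), as_tibble(mat))
  list(genotypes = geno,
       snp_info = tibble(snp_id = fix$ID, gene = fix$CHROM))
}

recode_to_minor <- function(parsed) {
  geno <- parsed$genotypes
  snps <- setdiff(names(geno), "subject_id")
  flipped <- logical(length(snps))
  for (i in seq_along(snps)) {
    v <- geno[[snps[i]]]
    if (all(is.na(v))) next
    freq <- mean(v, na.rm = TRUE) / 2
    if (freq > 0.5) {
      geno[[snps[i]]] <- 2L - v
      flipped[i] <- TRUE
    }
  }
  parsed$genotypes <- geno
  parsed$snp_info$flipped <- flipped
  parsed
}
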