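# Genotype quality control: MAF, call rates, heterozygosity outliers,
# Hardy-Weinberg equilibrium, LD r^2 and per-gene best-SNP selection.

#' Minor allele frequency
#'
#' Frequency of the less common allele among non-missing calls; invariant to
#' how the alleles were coded (always in \[0, 0.5\]).
#'
#' @param dosages Integer vector of allele counts (0/1/2, `NA` missing).
#' @return A single frequency, or `NA` if every call is missing.
#' @export
#' @examples
#' maf(rep(c(2, 1, 0), c(1, 45, 110)))  # 47/312
maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) return(NA_real_)
  if (any(!d %in% 0:2)) {
    abort("dosages must be 0, 1, 2 or NA.", class = "aldaphen_invalid_parameter")
  }
  freq <- mean(d) / 2
  min(freq, 1 - freq)
}

#' Hardy-Weinberg equilibrium tests from genotype counts
#'
#' Chi-square goodness-of-fit test (1 df) of the observed genotype counts
#' against the Hardy-Weinberg expectation computed from the observed allele
#' frequency, plus an exact test obtained by full enumeration of the possible
#' heterozygote counts conditional on the observed allele counts (two-sided:
#' the summed probability of all heterozygote counts no more probable than
#' the observed one).
#'
#' @param hom_minor,het,hom_major Genotype counts.
#' @return One-row tibble: `n`, `maf`, `chi2`, `p_chi2`, `p_exact`.
#'   Monomorphic SNPs give `chi2 = 0` and both p-values 1 by convention.
#' @export
#' @examples
#' hwe_test(34, 88, 34)  # chi2 = 2.56, p = 0.109
hwe_test <- function(hom_minor, het, hom_major) {
  counts <- c(hom_minor, het, hom_major)
  if (any(counts < 0) || any(counts != floor(counts)) || sum(counts) < 1) {
    abort("genotype counts must be non-negative integers with a positive total.",
          class = "aldaphen_invalid_parameter")
  }
  n <- sum(counts)
  n_minor <- 2 * hom_minor + het
  q <- n_minor / (2 * n)
  if (q == 0 || q == 1) {
    return(tibble(n = n, maf = min(q, 1 - q), chi2 = 0,
                  p_chi2 = 1, p_exact = 1))
  }
  expected <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  p_chi2 <- pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble(n = n, maf = min(q, 1 - q), chi2 = chi2, p_chi2 = p_chi2,
         p_exact = hwe_exact_p(hom_minor, het, hom_major))
}

# Exact HWE test (conditional enumeration): P(n_het | allele counts) follows
# the distribution of Levene/Haldane; two-sided p sums probabilities of all
# heterozygote counts at most as probable as the observed one.
hwe_exact_p <- function(hom_minor, het, hom_major) {
  n <- hom_minor + het + hom_major
  n_minor <- 2 * hom_minor + het
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  log_prob <- vapply(hets, function(h) {
    hm <- (n_minor - h) / 2
    hM <- n - h - hm
    lchoose(n, h) + lchoose(n - h, hm) + h * log(2) -
      lchoose(2 * n, n_minor)
  }, numeric(1))
  # lchoose(n-h, hm) counts the placement of minor homozygotes among the
  # remaining subjects; normalization is the usual 2N-choose-n_minor term.
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  observed <- prob[hets == het]
  sum(prob[prob <= observed + 1e-12])
}

#' Per-SNP and per-sample genotyping call rates
#'
#' @param genotypes Dosage tibble (`subject_id` + one column per SNP).
#' @return A list of tibbles: `snp` (`snp_id`, `call_rate`) and `sample`
#'   (`subject_id`, `call_rate`).
#' @export
call_rates <- function(genotypes) {
  geno <- as_tibble(genotypes)
  snps <- setdiff(names(geno), "subject_id")
  if (!length(snps) || !nrow(geno)) {
    abort("`genotypes` must contain at least one SNP column and one subject.",
          class = "aldaphen_invalid_parameter")
  }
  mat <- as.matrix(geno[snps])
  list(
    snp = tibble(snp_id = snps, call_rate = unname(colMeans(!is.na(mat)))),
    sample = tibble(subject_id = geno$subject_id,
                    call_rate = unname(rowMeans(!is.na(mat))))
  )
}

#' Heterozygosity outlier detection
#'
#' Computes each sample's heterozygosity rate (fraction of non-missing calls
#' with dosage 1) and flags samples outside mean +/- `n_sd` standard
#' deviations of the sample distribution. A zero-variance distribution flags
#' nobody.
#'
#' @inheritParams call_rates
#' @param n_sd Width of the acceptance band in standard deviations; default 3.
#' @return Tibble: `subject_id`, `het_rate`, `outlier`.
#' @export
het_outliers <- function(genotypes, n_sd = 3) {
  geno <- as_tibble(genotypes)
  snps <- setdiff(names(geno), "subject_id")
  if (nrow(geno) < 3L) {
    abort("need at least 3 samples to assess heterozygosity outliers.",
          class = "aldaphen_invalid_parameter")
  }
  mat <- as.matrix(geno[snps])
  het <- rowMeans(mat == 1L, na.rm = TRUE)
  het[is.nan(het)] <- NA_real_
  m <- mean(het, na.rm = TRUE)
  s <- sd(het, na.rm = TRUE)
  outlier <- if (is.na(s) || s == 0) {
    rep(FALSE, length(het))
  } else {
    !is.na(het) & (het < m - n_sd * s | het > m + n_sd * s)
  }
  tibble(subject_id = geno$subject_id, het_rate = het, outlier = outlier)
}

#' QC thresholds
#'
#' Defaults follow the conventional candidate-gene filter set: MAF >= 5%,
#' per-SNP call rate >= 97%, per-sample call rate >= 90%, sample
#' heterozygosity within mean +/- 3 sd. Hardy-Weinberg departures are
#' reported but non-fatal unless `hwe_p` is set.
#'
#' @param maf_min Minimum minor allele frequency (inclusive).
#' @param snp_call_rate Minimum per-SNP call rate (inclusive).
#' @param sample_call_rate Minimum per-sample call rate (inclusive).
#' @param het_sd Heterozygosity acceptance band width in sd units.
#' @param hwe_p Optional: exclude SNPs with HWE chi-square p below this.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, snp_call_rate = 0.97,
                          sample_call_rate = 0.90, het_sd = 3,
                          hwe_p = NULL) {
  structure(list(maf_min = maf_min, snp_call_rate = snp_call_rate,
                 sample_call_rate = sample_call_rate, het_sd = het_sd,
                 hwe_p = hwe_p),
            class = "qc_thresholds")
}

#' Apply genotype quality control
#'
#' Computes per-SNP statistics (MAF, call rate, HWE) and per-sample
#' statistics (call rate, heterozygosity) on the input table in a single
#' pass, then drops failing SNPs and samples. All decisions are recorded.
#'
#' @inheritParams call_rates
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `qc_result`: `genotypes` (filtered), `snp_report`
#'   (per SNP: statistics, per-criterion pass flags, `pass`), and
#'   `sample_report` (per sample likewise).
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  geno <- as_tibble(genotypes)
  snps <- setdiff(names(geno), "subject_id")
  cr <- call_rates(geno)
  het <- het_outliers(geno, n_sd = thresholds$het_sd)

  snp_stats <- purrr::map_dfr(snps, function(s) {
    d <- geno[[s]]
    counts <- c(sum(d == 2L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                sum(d == 0L, na.rm = TRUE))
    hwe <- if (sum(counts) > 0) hwe_test(counts[1], counts[2], counts[3])
           else tibble(chi2 = NA_real_, p_chi2 = NA_real_, p_exact = NA_real_)
    tibble(snp_id = s, maf = maf(d),
           call_rate = cr$snp$call_rate[cr$snp$snp_id == s],
           hwe_chi2 = hwe$chi2, hwe_p = hwe$p_chi2, hwe_p_exact = hwe$p_exact)
  })
  snp_report <- dplyr::mutate(
    snp_stats,
    pass_maf = !is.na(.data$maf) & .data$maf >= thresholds$maf_min,
    pass_call_rate = .data$call_rate >= thresholds$snp_call_rate,
    pass_hwe = if (is.null(thresholds$hwe_p)) TRUE
               else !is.na(.data$hwe_p) & .data$hwe_p >= thresholds$hwe_p,
    pass = .data$pass_maf & .data$pass_call_rate & .data$pass_hwe
  )
  sample_report <- dplyr::mutate(
    dplyr::left_join(cr$sample, het, by = "subject_id"),
    pass_call_rate = .data$call_rate >= thresholds$sample_call_rate,
    pass_het = !.data$outlier,
    pass = .data$pass_call_rate & .data$pass_het
  )

  kept_snps <- snp_report$snp_id[snp_report$pass]
  kept_samples <- sample_report$subject_id[sample_report$pass]
  filtered <- geno[geno$subject_id %in% kept_samples,
                   c("subject_id", kept_snps), drop = FALSE]
  if (!length(kept_snps) || !nrow(filtered)) {
    warn("quality control removed every SNP or every sample.")
  }
  structure(list(genotypes = filtered, snp_report = snp_report,
                 sample_report = sample_report, thresholds = thresholds),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d/%d SNPs and %d/%d samples retained\n",
              sum(x$snp_report$pass), nrow(x$snp_report),
              sum(x$sample_report$pass), nrow(x$sample_report)))
  print(x$snp_report)
  invisible(x)
}

#' Linkage-disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors over subjects with both
#' calls observed. Allele-coding invariant.
#'
#' @param dosages_a,dosages_b Integer dosage vectors of equal length.
#' @return r^2 in \[0, 1\], or `NA` when fewer than two complete pairs exist
#'   or either vector is constant.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) {
    abort("dosage vectors must have equal length.",
          class = "aldaphen_consistency_error")
  }
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]
  b <- dosages_b[ok]
  if (length(a) < 2L || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Select the best SNP per gene
#'
#' Mirrors the candidate-gene selection procedure: among a gene's
#' post-QC SNPs, (1) prune pairs in linkage disequilibrium above
#' `r2_threshold`, keeping the member with the smaller non-parametric
#' association p-value against the phenotype; (2) return the surviving SNP
#' with the smallest p-value (Kruskal-Wallis across codominant dosage
#' groups; Wilcoxon when only two groups are present). Ties break by SNP id.
#' This "best SNP" selection optimizes observed significance and is, by
#' construction, selection-biased; it reproduces the procedure, not an
#' unbiased estimate.
#'
#' @inheritParams call_rates
#' @param gene_map Tibble with `snp_id`, `gene`.
#' @param gene Gene label to select within.
#' @param phenotype Numeric phenotype vector aligned with the rows of
#'   `genotypes` (typically the Total Score).
#' @param r2_threshold LD pruning threshold; default 0.05.
#' @return The selected SNP id (character scalar) with attribute
#'   `"candidates"`: a tibble of every considered SNP, its p-value and
#'   whether LD pruning removed it.
#' @export
select_best_snp <- function(genotypes, gene_map, gene, phenotype,
                            r2_threshold = 0.05) {
  geno <- as_tibble(genotypes)
  snps <- intersect(gene_map$snp_id[gene_map$gene == gene],
                    setdiff(names(geno), "subject_id"))
  if (!length(snps)) {
    abort(sprintf("no SNPs available for gene '%s' after QC.", gene),
          class = "aldaphen_empty_selection")
  }
  pvals <- vapply(snps, function(s) {
    snp_assoc_p(geno[[s]], phenotype)
  }, numeric(1))
  pruned <- character(0)
  active <- snps[order(pvals[snps], snps)]
  i <- 1
  while (i < length(active)) {
    j <- i + 1
    while (j <= length(active)) {
      r2 <- ld_r2(geno[[active[i]]], geno[[active[j]]])
      if (!is.na(r2) && r2 > r2_threshold) {
        pruned <- c(pruned, active[j])  # active is p-ordered: keep the stronger
        active <- active[-j]
      } else {
        j <- j + 1
      }
    }
    i <- i + 1
  }
  best <- active[order(pvals[active], active)][1]
  structure(best, candidates = tibble(
    snp_id = snps, gene = gene, p = unname(pvals[snps]),
    pruned = snps %in% pruned, selected = snps == best
  ))
}

# Non-parametric single-SNP association used inside selection: dosage groups
# (codominant) against a continuous phenotype.
snp_assoc_p <- function(dosages, phenotype) {
  ok <- !is.na(dosages) & !is.na(phenotype)
  d <- factor(dosages[ok], levels = 0:2)
  d <- droplevels(d)
  y <- phenotype[ok]
  if (nlevels(d) < 2L || length(unique(y)) < 2L) return(1)
  if (nlevels(d) == 2L) {
    assoc_continuous(y, d)$p
  } else {
    kruskal.test(y, d)$p.value
  }
}
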