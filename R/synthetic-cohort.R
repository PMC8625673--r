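#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Samples minor-allele dosages (0/1/2) i.i.d. with the Hardy-Weinberg
#' genotype probabilities `(1-q)^2`, `2q(1-q)`, `q^2` for minor-allele
#' frequency `q`.
#'
#' @param freq Minor-allele frequency in \[0, 1\].
#' @param n Number of subjects.
#' @param seed Optional integer seed (a dedicated sub-stream is used so the
#'   caller's RNG state is untouched).
#' @return Integer vector of length `n` with values in \{0, 1, 2\}.
#' @export
#' @examples
#' table(sample_genotypes(0.15, 1000, seed = 1))
sample_genotypes <- function(freq, n, seed = NULL) {
  assert_proportion(freq, "freq")
  n <- assert_count(n, "n")
  draw <- function() {
    sample(0:2, n, replace = TRUE,
           prob = c((1 - freq)^2, 2 * freq * (1 - freq), freq^2))
  }
  if (is.null(seed)) draw() else with_substream(seed, "genotypes", draw())
}

#' Generate a synthetic lithium-response cohort
#'
#' Draws per-subject Alda ratings, demographics and SNP genotypes with the
#' marginal structure described by a [cohort_params()] object. The latent A
#' score is Normal, shifted additively by `effect_map` per copy of each minor
#' allele (using the true genotype, before any missingness masking), then
#' rounded half-away-from-zero and clipped to the integer 0-10 scale. B items
#' are drawn independently from their categorical distributions. Genotypes
#' are drawn under Hardy-Weinberg equilibrium and masked missing at
#' `missing_rate_geno`.
#'
#' All draws come from documented sub-streams of `params$seed`, so the output
#' is reproducible and each component (ages, genotypes of each SNP, ...) is
#' stable when unrelated parameters change.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `alda_cohort` with elements
#'   * `cohort`: tibble with `subject_id`, `a_score`, `b1`..`b5`, `age`, `sex`;
#'   * `genotypes`: tibble with `subject_id` and one integer dosage column per
#'     SNP (`NA` = missing call);
#'   * `snp_info`: the `snp_specs` used.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_params(seed = 7))
#' sim$cohort
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    abort("`params` must be created with cohort_params().",
          class = "aldaphen_invalid_parameter")
  }
  n <- params$n_subjects
  seed <- params$seed
  subject_id <- sprintf("S%04d", seq_len(n))

  age <- with_substream(seed, "age", rnorm(n, params$age_mean, params$age_sd))
  sex <- with_substream(seed, "sex", ifelse(
    rbinom(n, 1, params$female_fraction) == 1, "female", "male"
  ))

  snps <- params$snp_specs
  dosage_true <- matrix(0L, nrow = n, ncol = nrow(snps),
                        dimnames = list(NULL, snps$snp_id))
  for (j in seq_len(nrow(snps))) {
    dosage_true[, j] <- with_substream(
      seed, paste0("geno:", snps$snp_id[j]),
      sample_genotypes(snps$maf[j], n)
    )
  }

  a_latent <- with_substream(seed, "a_score", rnorm(n, params$a_mean, params$a_sd))
  for (snp in names(params$effect_map)) {
    a_latent <- a_latent + params$effect_map[[snp]] * dosage_true[, snp]
  }
  a_score <- as.integer(pmin(10, pmax(0, round_half_away(a_latent))))

  b <- matrix(0L, nrow = n, ncol = 5, dimnames = list(NULL, paste0("b", 1:5)))
  for (i in 1:5) {
    b[, i] <- with_substream(
      seed, paste0("b_item:", i),
      sample(0:2, n, replace = TRUE, prob = params$b_item_probs[i, ])
    )
  }

  dosage <- dosage_true
  if (params$missing_rate_geno > 0) {
    miss <- with_substream(
      seed, "missingness",
      matrix(rbinom(n * ncol(dosage), 1, params$missing_rate_geno) == 1,
             nrow = n)
    )
    dosage[miss] <- NA_integer_
  }

  cohort <- tibble(
    subject_id = subject_id,
    a_score = a_score,
    b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], b4 = b[, 4], b5 = b[, 5],
    age = age,
    sex = sex
  )
  genotypes <- dplyr::bind_cols(
    tibble(subject_id = subject_id),
    as_tibble(dosage)
  )
  structure(
    list(cohort = cohort, genotypes = genotypes, snp_info = snps),
    class = "alda_cohort"
  )
}

#' @export
print.alda_cohort <- function(x, ...) {
  cat(sprintf("<alda_cohort> %d subjects, %d SNPs\n",
              nrow(x$cohort), nrow(x$snp_info)))
  print(x$cohort, n = 5)
  invisible(x)
}

#' Write a cohort to delimited text and VCF
#'
#' Emits the cohort table as tab-delimited text, the genotype matrix as a
#' dosage TSV (subjects x SNPs, minor-allele counts, empty cell = missing),
#' and a minimal VCF v4.2 with a GT-only FORMAT field. Dosages 0/1/2 map to
#' `0/0`, `0/1`, `1/1` with the minor allele as ALT; missing calls are `./.`.
#'
#' @param cohort Tibble as produced by [generate_cohort()] (`$cohort`).
#' @param genotypes Dosage tibble (`$genotypes`), subject ids must match
#'   `cohort` exactly.
#' @param out_dir Output directory (created if needed).
#' @param snp_info Optional tibble with `snp_id`, `gene`, `major_allele`,
#'   `minor_allele`; defaults are synthesized when absent.
#' @return Invisibly, a named character vector of the three file paths
#'   (`cohort`, `dosage`, `vcf`).
#' @export
write_cohort <- function(cohort, genotypes, out_dir, snp_info = NULL) {
  if (!identical(cohort$subject_id, genotypes$subject_id)) {
    abort("`cohort` and `genotypes` must list the same subjects in the same order.",
          class = "aldaphen_consistency_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  snp_ids <- setdiff(names(genotypes), "subject_id")
  if (is.null(snp_info)) {
    snp_info <- tibble(snp_id = snp_ids, gene = snp_ids,
                       major_allele = "A", minor_allele = "B")
  }
  snp_info <- as_tibble(snp_info)[match(snp_ids, snp_info$snp_id), ]

  paths <- c(
    cohort = file.path(out_dir, "cohort.tsv"),
    dosage = file.path(out_dir, "genotypes_dosage.tsv"),
    vcf = file.path(out_dir, "genotypes.vcf")
  )
  readr::write_tsv(cohort, paths[["cohort"]])
  readr::write_tsv(genotypes, paths[["dosage"]])

  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_along(snp_ids), function(j) {
    d <- genotypes[[snp_ids[j]]]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(snp_info$gene[j], j, snp_ids[j],
            snp_info$major_allele[j], snp_info$minor_allele[j],
            ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=aldaphen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$subject_id), collapse = "\t")
  )
  writeLines(c(header, body), paths[["vcf"]])
  invisible(paths)
}
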