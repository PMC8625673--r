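#' Default SNP specifications for the synthetic cohort
#'
#' One proxy SNP per candidate circadian gene, with minor-allele frequencies
#' derived from the reference genotype counts used throughout the package
#' (RORA rs17204910 CC:34/TC:88/TT:34, PPARGC1A rs2932965 AA:23/AG:79/GG:53,
#' TIMELESS rs774045 AA:1/AG:45/GG:110).
#'
#' @return A tibble with columns `snp_id`, `gene`, `maf`, `major_allele`,
#'   `minor_allele`.
#' @export
#' @examples
#' default_snp_specs()
default_snp_specs <- function() {
  tibble(
    snp_id = c("rs17204910", "rs2932965", "rs774045"),
    gene = c("RORA", "PPARGC1A", "TIMELESS"),
    maf = c(0.5, 125 / 310, 47 / 312),
    major_allele = c("C", "G", "G"),
    minor_allele = c("T", "A", "A")
  )
}

#' Default B-item score distributions
#'
#' Prevalence of raw scores 0/1/2 on the five Alda B items in the reference
#' sample (counts 112:45:8, 100:57:8, 122:15:28, 18:140:7, 57:63:45),
#' normalized to probabilities.
#'
#' @return A 5 x 3 matrix; rows `b1`..`b5`, columns scores `0`,`1`,`2`.
#' @export
default_b_item_probs <- function() {
  counts <- rbind(
    b1 = c(112, 45, 8),
    b2 = c(100, 57, 8),
    b3 = c(122, 15, 28),
    b4 = c(18, 140, 7),
    b5 = c(57, 63, 45)
  )
  colnames(counts) <- c("0", "1", "2")
  counts / rowSums(counts)
}

#' Parameters for the synthetic cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. The defaults
#' reproduce the reference sample's marginal structure: n = 164 subjects, 60%
#' female, age ~ Normal(44.70, 12.29), Alda A score ~ Normal(6.33, 2.99)
#' discretized to the 0-10 scale, B-item prevalences from
#' [default_b_item_probs()], and one Hardy-Weinberg SNP per gene from
#' [default_snp_specs()].
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param female_fraction Proportion of female subjects.
#' @param age_mean,age_sd Age distribution in years.
#' @param a_mean,a_sd Latent Alda A-score distribution before discretization.
#' @param b_item_probs 5 x 3 matrix of per-item probabilities over scores
#'   \{0, 1, 2\}; each row must sum to 1.
#' @param snp_specs Tibble with columns `snp_id`, `gene`, `maf` (and
#'   optionally `major_allele`, `minor_allele`).
#' @param effect_map Named numeric vector: additive shift of the latent A
#'   score per copy of the minor allele, names matching `snp_id`s. Empty by
#'   default (no planted genotype effect).
#' @param missing_rate_geno Per-call probability that a genotype is masked
#'   missing.
#' @param seed Integer seed; every random sub-stream is derived from it.
#' @return An object of class `cohort_params`.
#' @export
#' @examples
#' cohort_params(n_subjects = 200, seed = 42)
cohort_params <- function(n_subjects = 164,
                          female_fraction = 0.60,
                          age_mean = 44.70,
                          age_sd = 12.29,
                          a_mean = 6.33,
                          a_sd = 2.99,
                          b_item_probs = default_b_item_probs(),
                          snp_specs = default_snp_specs(),
                          effect_map = numeric(0),
                          missing_rate_geno = 0,
                          seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  assert_proportion(female_fraction, "female_fraction")
  assert_scalar_number(age_mean, "age_mean")
  assert_scalar_number(age_sd, "age_sd", lower = 0)
  assert_scalar_number(a_mean, "a_mean")
  assert_scalar_number(a_sd, "a_sd", lower = 0)
  assert_proportion(missing_rate_geno, "missing_rate_geno")
  seed <- assert_count(seed, "seed", lower = 0L)

  b_item_probs <- as.matrix(b_item_probs)
  if (!identical(dim(b_item_probs), c(5L, 3L)) ||
      any(b_item_probs < 0) ||
      any(abs(rowSums(b_item_probs) - 1) > 1e-12)) {
    abort("`b_item_probs` must be a 5 x 3 matrix of probabilities with rows summing to 1.",
          class = "aldaphen_invalid_parameter")
  }
  rownames(b_item_probs) <- paste0("b", 1:5)

  snp_specs <- as_tibble(snp_specs)
  required <- c("snp_id", "gene", "maf")
  if (!all(required %in% names(snp_specs))) {
    abort("`snp_specs` needs columns snp_id, gene, maf.",
          class = "aldaphen_invalid_parameter")
  }
  if (any(snp_specs$maf < 0 | snp_specs$maf > 1)) {
    abort("`snp_specs$maf` must lie in [0, 1].",
          class = "aldaphen_invalid_parameter")
  }
  if (anyDuplicated(snp_specs$snp_id)) {
    abort("`snp_specs$snp_id` must be unique.", class = "aldaphen_invalid_parameter")
  }
  if (!"major_allele" %in% names(snp_specs)) snp_specs$major_allele <- "A"
  if (!"minor_allele" %in% names(snp_specs)) snp_specs$minor_allele <- "B"

  if (length(effect_map)) {
    if (is.null(names(effect_map)) ||
        !all(names(effect_map) %in% snp_specs$snp_id)) {
      abort("`effect_map` must be named by SNP ids present in `snp_specs`.",
            class = "aldaphen_invalid_parameter")
    }
  }

  structure(
    list(
      n_subjects = n_subjects, female_fraction = female_fraction,
      age_mean = age_mean, age_sd = age_sd, a_mean = a_mean, a_sd = a_sd,
      b_item_probs = b_item_probs, snp_specs = snp_specs,
      effect_map = effect_map, missing_rate_geno = missing_rate_geno,
      seed = seed
    ),
    class = "cohort_params"
  )
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params>\n")
  cat(sprintf("  n_subjects: %d (female fraction %.2f)\n", x$n_subjects, x$female_fraction))
  cat(sprintf("  age ~ N(%.2f, %.2f); latent A ~ N(%.2f, %.2f)\n",
              x$age_mean, x$age_sd, x$a_mean, x$a_sd))
  cat(sprintf("  SNPs: %s\n", paste(x$snp_specs$snp_id, collapse = ", ")))
  cat(sprintf("  planted effects: %s; genotype missing rate: %.3f; seed: %d\n",
              if (length(x$effect_map)) paste(names(x$effect_map), x$effect_map,
                                              sep = "=", collapse = ", ") else "none",
              x$missing_rate_geno, x$seed))
  invisible(x)
}
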