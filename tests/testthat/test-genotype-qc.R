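ref_counts <- list(
  RORA = c(hom_minor = 34, het = 88, hom_major = 34),
  PPARGC1A = c(hom_minor = 23, het = 79, hom_major = 53),
  TIMELESS = c(hom_minor = 1, het = 45, hom_major = 110)
)

test_that("minor allele frequency counts alleles among non-missing calls", {
  tim <- rep(c(2, 1, 0), ref_counts$TIMELESS)
  expect_equal(maf(tim), 47 / 312, tolerance = 1e-12)
  rora <- rep(c(2, 1, 0), ref_counts$RORA)
  expect_equal(maf(rora), 0.5)
  expect_equal(maf(c(0, 0, 0)), 0)
  expect_true(is.na(maf(c(NA, NA))))
  expect_equal(maf(c(2, 2, NA)), 0)  # coding-invariant: always <= 0.5
  # allele-label swap invariance
  set.seed(1)
  d <- sample(0:2, 50, replace = TRUE)
  expect_equal(maf(d), maf(2 - d))
})

test_that("Hardy-Weinberg chi-square matches hand-computed reference values", {
  r <- hwe_test(34, 88, 34)
  expect_equal(r$chi2, 2.5641026, tolerance = 1e-6)
  expect_equal(r$p_chi2, 0.1093146, tolerance = 1e-6)
  t <- hwe_test(1, 45, 110)
  expect_equal(t$chi2, 2.53, tolerance = 0.01)
  expect_equal(t$p_chi2, 0.112, tolerance = 0.01)
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_chi2, 1)
  mono <- hwe_test(0, 0, 42)
  expect_equal(mono$p_chi2, 1)
  expect_equal(mono$p_exact, 1)
})

test_that("the exact HWE test matches an independent enumeration reference", {
  # reference: Levene/Haldane conditional probabilities written directly from
  # log-factorials, independent of the package's implementation
  exact_ref <- function(hm, h, hM) {
    n <- hm + h + hM
    na <- 2 * hm + h
    hets <- seq(na %% 2, min(na, 2 * n - na), 2)
    pr <- vapply(hets, function(k) {
      m <- (na - k) / 2
      M <- n - k - m
      exp(lfactorial(n) - lfactorial(m) - lfactorial(k) - lfactorial(M) +
            k * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
            lfactorial(2 * n))
    }, numeric(1))
    sum(pr[pr <= pr[hets == h] * (1 + 1e-9)])
  }
  set.seed(11)
  max_tail_gap <- 0
  for (i in 1:1000) {
    n <- sample(50:300, 1)
    q <- runif(1, 0.15, 0.5)
    mult <- sample(c(0.5, 0.7, 1, 1.4, 1.8), 1)  # includes HWE departures
    pr <- c((1 - q)^2, 2 * q * (1 - q) * mult, q^2)
    g <- sample(0:2, n, replace = TRUE, prob = pr / sum(pr))
    counts <- c(sum(g == 2), sum(g == 1), sum(g == 0))
    r <- hwe_test(counts[1], counts[2], counts[3])
    expect_equal(r$p_exact, exact_ref(counts[1], counts[2], counts[3]),
                 tolerance = 1e-9)
    # in the decision-relevant tail the two tests must agree closely
    qh <- (2 * counts[1] + counts[2]) / (2 * n)
    expected <- n * c(qh^2, 2 * qh * (1 - qh), (1 - qh)^2)
    if (all(expected >= 5) && (r$p_chi2 < 0.05 || r$p_exact < 0.05)) {
      max_tail_gap <- max(max_tail_gap, abs(r$p_exact - r$p_chi2))
    }
  }
  expect_lt(max_tail_gap, 0.05)
})

test_that("call rates are per-SNP and per-sample fractions of observed calls", {
  geno <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:100),
    snpA = c(rep(NA_integer_, 3), rep(1L, 97)),
    snpB = rep(0L, 100)
  )
  cr <- call_rates(geno)
  expect_equal(cr$snp$call_rate, c(0.97, 1))
  expect_equal(cr$sample$call_rate[1:3], rep(0.5, 3))
  geno$snpB[1] <- NA_integer_
  geno$snpA[1] <- NA_integer_
  expect_equal(call_rates(geno)$sample$call_rate[1], 0)
})

test_that("heterozygosity outliers are flagged outside the 3-sd band", {
  set.seed(5)
  n_snp <- 40
  mat <- matrix(rbinom(100 * n_snp, 1, 0.35), nrow = 100)  # het indicators
  mat[100, ] <- 1L  # planted extreme sample: heterozygous everywhere
  geno <- tibble::as_tibble(mat, .name_repair = ~ paste0("s", seq_len(n_snp)))
  geno <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("P%03d", 1:100)),
                           geno)
  flags <- het_outliers(geno)
  expect_true(flags$outlier[100])
  expect_lt(sum(flags$outlier), 5)
  # zero variance: nobody flagged
  uni <- dplyr::mutate(geno, dplyr::across(-subject_id, ~1L))
  expect_false(any(het_outliers(uni)$outlier))
  # permutation invariance of the number of flags
  perm <- geno[sample(100), ]
  expect_equal(sum(het_outliers(perm)$outlier), sum(flags$outlier))
})

test_that("QC applies the documented inclusive boundaries", {
  n <- 100
  geno <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    rare = c(rep(1L, 8), rep(0L, 92)),                 # maf 0.04 -> excluded
    edge = c(rep(NA_integer_, 3), rep(c(0L, 1L), c(57, 40))),  # call rate 0.97
    common = rep(c(0L, 1L, 2L), c(36, 48, 16))
  )
  qc <- apply_qc(geno)
  expect_false(qc$snp_report$pass[qc$snp_report$snp_id == "rare"])
  expect_true(qc$snp_report$pass[qc$snp_report$snp_id == "edge"])
  expect_true("common" %in% names(qc$genotypes))
  expect_false("rare" %in% names(qc$genotypes))
})

test_that("clean tables pass QC unchanged and QC is idempotent", {
  sim <- make_cohort(seed = 14, n = 300, missing = 0.01)
  qc1 <- apply_qc(sim$genotypes)
  expect_equal(sum(!qc1$snp_report$pass), 0)
  qc2 <- apply_qc(qc1$genotypes)
  expect_identical(as.data.frame(qc2$genotypes), as.data.frame(qc1$genotypes))
})

test_that("ld_r2 is a coding-invariant squared correlation", {
  set.seed(3)
  a <- sample(0:2, 200, replace = TRUE)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2L - a), 1)  # allele-swap invariance
  expect_true(is.na(ld_r2(a, rep(1L, 200))))
  b <- a
  b[1:3] <- NA
  expect_equal(ld_r2(a, b), 1)  # pairwise-complete
})

test_that("independently simulated SNPs show near-zero LD", {
  exceed <- 0L
  for (seed in 1:100) {
    a <- sample_genotypes(0.3, 10000, seed = seed)
    b <- sample_genotypes(0.3, 10000, seed = seed + 5000)
    if (ld_r2(a, b) >= 0.01) exceed <- exceed + 1L
  }
  expect_lte(exceed, 1L)  # r^2 < 0.01 in >= 99% of seeds
})

test_that("best-SNP selection prunes LD twins and prefers the causal SNP", {
  geno1 <- tibble::tibble(subject_id = as.character(1:50),
                          s1 = sample_genotypes(0.3, 50, seed = 2))
  gm1 <- tibble::tibble(snp_id = "s1", gene = "G")
  expect_equal(as.character(select_best_snp(geno1, gm1, "G", rnorm(50))), "s1")
  expect_error(select_best_snp(geno1, gm1, "H", rnorm(50)),
               class = "aldaphen_empty_selection")

  # two perfectly correlated SNPs: exactly one survives pruning
  geno2 <- dplyr::mutate(geno1, s2 = s1)
  gm2 <- tibble::tibble(snp_id = c("s1", "s2"), gene = "G")
  sel <- select_best_snp(geno2, gm2, "G", rnorm(50))
  cand <- attr(sel, "candidates")
  expect_equal(sum(cand$pruned), 1)
  expect_equal(sum(cand$selected), 1)

  # planted causal SNP among 5 null SNPs: selected in >= 90% of seeds
  hits <- 0L
  for (seed in 1:100) {
    n <- 500
    mat <- sapply(1:6, function(j) sample_genotypes(0.3, n, seed = 600 * seed + j))
    colnames(mat) <- paste0("snp", 1:6)
    set.seed(seed)
    ts <- rnorm(n) + 1.0 * (mat[, "snp3"] >= 1)  # dominant effect, d = 1
    geno <- dplyr::bind_cols(tibble::tibble(subject_id = as.character(1:n)),
                             tibble::as_tibble(mat))
    gm <- tibble::tibble(snp_id = colnames(mat), gene = "G")
    if (as.character(select_best_snp(geno, gm, "G", ts)) == "snp3") {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 90L)
})

test_that("VCF genotypes are re-expressed as minor-allele dosages", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "A1", "A2", "A3"), collapse = "\t"),
    paste(c("g1", "1", "snpX", "C", "T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "./."), collapse = "\t"),
    # ALT is the major allele here: dosages must be flipped on read
    paste(c("g1", "2", "snpY", "G", "A", ".", "PASS", ".", "GT",
            "1/1", "1/1", "0/1"), collapse = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  rg <- read_genotypes(path)
  expect_equal(rg$genotypes$snpX, c(0L, 1L, NA_integer_))
  expect_equal(rg$genotypes$snpY, c(0L, 0L, 1L))
  expect_equal(rg$snp_info$flipped, c(FALSE, TRUE))
  expect_equal(rg$snp_info$gene, c("g1", "g1"))
})

test_that("malformed dosage files report the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tsnp1", "S1\t1", "S2\t7"), path)
  expect_error(read_genotypes(path), "line 3",
               class = "aldaphen_parse_error")
  expect_error(read_genotypes("/nonexistent/file.tsv"),
               class = "aldaphen_io_error")
})
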