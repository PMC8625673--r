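# Non-parametric single-SNP association tests and the phenotype x SNP scan.

#' Code dosages into genotype groups
#'
#' Dominant coding contrasts carriers of the minor allele (dosage >= 1)
#' against non-carriers; codominant coding keeps the three dosage groups.
#' Missing calls are dropped by the association functions.
#'
#' @param dosages Integer vector of minor-allele dosages (0/1/2, `NA`
#'   missing).
#' @param coding `"dominant"` or `"codominant"`.
#' @return A factor (`non-carrier`/`carrier`, or `hom-major`/`het`/
#'   `hom-minor`), `NA` preserved.
#' @export
#' @examples
#' code_genotype(c(0, 1, 2), "dominant")
code_genotype <- function(dosages, coding = c("dominant", "codominant")) {
  coding <- match.arg(coding)
  if (any(!is.na(dosages) & !dosages %in% 0:2)) {
    abort("dosages must be 0, 1, 2 or NA.", class = "aldaphen_invalid_parameter")
  }
  out <- if (coding == "dominant") {
    factor(ifelse(dosages >= 1, "carrier", "non-carrier"),
           levels = c("non-carrier", "carrier"))
  } else {
    factor(c("hom-major", "het", "hom-minor")[dosages + 1L],
           levels = c("hom-major", "het", "hom-minor"))
  }
  if (nlevels(droplevels(out[!is.na(out)])) < 2L) {
    abort(sprintf("%s coding yields fewer than 2 non-empty groups.", coding),
          class = "aldaphen_degenerate_coding")
  }
  out
}

#' Association between a categorical phenotype and genotype groups
#'
#' Pearson chi-square (no continuity correction) on the groups x classes
#' contingency table; for 2 x 2 tables with any expected cell count below 5
#' the two-sided Fisher exact test is used instead.
#'
#' @param labels Binary phenotype labels (e.g. GR/NR factor).
#' @param groups Genotype group factor from [code_genotype()].
#' @return One-row tibble: `test`, `statistic`, `df`, `p`, `neglog10p`.
#' @export
assoc_categorical <- function(labels, groups) {
  ok <- !is.na(labels) & !is.na(groups)
  g <- droplevels(factor(groups[ok]))
  y <- droplevels(factor(labels[ok]))
  if (nlevels(g) < 2L || nlevels(y) < 2L) {
    abort("need at least two non-empty groups and two classes.",
          class = "aldaphen_degenerate_coding")
  }
  tab <- table(g, y)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2L, 2L)) && any(expected < 5)) {
    p <- fisher.test(tab)$p.value
    return(tibble(test = "fisher", statistic = NA_real_, df = NA_integer_,
                  p = p, neglog10p = -log10(p)))
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(test = "pearson-chisq", statistic = unname(res$statistic),
         df = as.integer(res$parameter), p = res$p.value,
         neglog10p = -log10(res$p.value))
}

#' Association between a continuous phenotype and genotype groups
#'
#' Two groups: two-sided Wilcoxon rank-sum test — exact (full enumeration of
#' group assignments, valid under ties) when both groups have at most 10
#' observations, otherwise the normal approximation with tie correction and
#' no continuity correction. Three or more groups: Kruskal-Wallis with tie
#' correction. Identical values everywhere give p = 1.
#'
#' @param values Numeric phenotype vector.
#' @param groups Genotype group factor.
#' @return One-row tibble: `test`, `statistic`, `df`, `p`, `neglog10p`.
#' @export
#' @examples
#' assoc_continuous(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$p  # 0.10
assoc_continuous <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  g <- droplevels(factor(groups[ok]))
  y <- values[ok]
  if (nlevels(g) < 2L || any(table(g) < 1L)) {
    abort("need at least two non-empty groups.",
          class = "aldaphen_degenerate_coding")
  }
  if (length(unique(y)) < 2L) {
    return(tibble(test = "degenerate", statistic = 0, df = NA_integer_,
                  p = 1, neglog10p = 0))
  }
  if (nlevels(g) == 2L) {
    n1 <- sum(g == levels(g)[1])
    n2 <- sum(g == levels(g)[2])
    if (n1 <= 10 && n2 <= 10) {
      p <- wilcoxon_exact_p(y[g == levels(g)[1]], y[g == levels(g)[2]])
      return(tibble(test = "wilcoxon-exact",
                    statistic = sum(rank(y)[g == levels(g)[1]]) - n1 * (n1 + 1) / 2,
                    df = NA_integer_, p = p, neglog10p = -log10(p)))
    }
    res <- suppressWarnings(wilcox.test(y ~ g, exact = FALSE, correct = FALSE))
    return(tibble(test = "wilcoxon-normal", statistic = unname(res$statistic),
                  df = NA_integer_, p = res$p.value,
                  neglog10p = -log10(res$p.value)))
  }
  res <- kruskal.test(y, g)
  tibble(test = "kruskal-wallis", statistic = unname(res$statistic),
         df = as.integer(res$parameter), p = res$p.value,
         neglog10p = -log10(res$p.value))
}

# Exact two-sided rank-sum p by complete enumeration of the assignments of
# the pooled observations to the first group; valid in the presence of ties.
wilcoxon_exact_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  r <- rank(pooled)
  n1 <- length(x1)
  idx <- combn(length(pooled), n1)
  sums <- colSums(matrix(r[idx], nrow = n1))
  observed <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(observed - mu) - 1e-9)
}

#' Scan all phenotypes against all selected SNPs
#'
#' Tests the five lithium-response phenotypes against each SNP under its
#' per-gene genotype coding: the categorical phenotypes (`alda_cat`,
#' `algo_cat`) via [assoc_categorical()], the continuous ones (`ts`,
#' `a_low_b` on its observed subsample, `grp`) via [assoc_continuous()].
#' Each result carries `-log10(p)` and a multiple-testing tier:
#' `fully-corrected` when `p < full_threshold` (default 0.003, 3 genes x 5
#' phenotypes), `gene-corrected` when `p < gene_threshold` (default 0.017, 3
#' genes), otherwise `none` — both strict inequalities.
#'
#' @param phenotypes A [phenotype_table()] tibble (columns `subject_id`,
#'   `ts`, `alda_cat`, `a_low_b`, `algo_cat`, `grp`).
#' @param genotypes Dosage tibble (`subject_id` + SNP columns); subjects are
#'   matched to `phenotypes` by id.
#' @param coding_map Tibble with `snp_id`, `gene`, `coding`
#'   (`"dominant"`/`"codominant"`).
#' @param gene_threshold,full_threshold Significance tiers (strict).
#' @return Tibble with one row per SNP x phenotype: `snp_id`, `gene`,
#'   `phenotype`, `coding`, `n`, `test`, `statistic`, `df`, `p`,
#'   `neglog10p`, `tier`.
#' @export
association_scan <- function(phenotypes, genotypes, coding_map,
                             gene_threshold = 0.017, full_threshold = 0.003) {
  ph <- as_tibble(phenotypes)
  geno <- as_tibble(genotypes)
  needed <- c("ts", "alda_cat", "a_low_b", "algo_cat", "grp")
  if (!all(c("subject_id", needed) %in% names(ph))) {
    abort("`phenotypes` must contain subject_id and the five phenotype columns.",
          class = "aldaphen_configuration_error")
  }
  merged <- dplyr::inner_join(ph, geno, by = "subject_id")
  if (!nrow(merged)) {
    abort("no overlapping subjects between phenotypes and genotypes.",
          class = "aldaphen_consistency_error")
  }
  specs <- list(
    list(name = "ts", kind = "continuous"),
    list(name = "alda_cat", kind = "categorical"),
    list(name = "a_low_b", kind = "continuous"),
    list(name = "algo_cat", kind = "categorical"),
    list(name = "grp", kind = "continuous")
  )
  rows <- list()
  for (i in seq_len(nrow(coding_map))) {
    snp <- coding_map$snp_id[i]
    groups <- code_genotype(merged[[snp]], coding_map$coding[i])
    for (spec in specs) {
      v <- merged[[spec$name]]
      keep <- !is.na(v) & !is.na(groups)
      degenerate <- nlevels(droplevels(factor(groups[keep]))) < 2L ||
        (spec$kind == "categorical" &&
           nlevels(droplevels(factor(v[keep]))) < 2L)
      res <- if (degenerate) {
        # single-class phenotype or single genotype group: the test is
        # undefined; report an explicit marker row instead of a p-value
        tibble(test = "degenerate", statistic = NA_real_, df = NA_integer_,
               p = NA_real_, neglog10p = NA_real_)
      } else if (spec$kind == "categorical") {
        assoc_categorical(v[keep], groups[keep])
      } else {
        assoc_continuous(as.numeric(v[keep]), groups[keep])
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(snp_id = snp, gene = coding_map$gene[i],
               phenotype = spec$name, coding = coding_map$coding[i],
               n = sum(keep)),
        res
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, tier = dplyr::case_when(
    is.na(.data$p) ~ "none",
    .data$p < full_threshold ~ "fully-corrected",
    .data$p < gene_threshold ~ "gene-corrected",
    TRUE ~ "none"
  ))
}

#' Bar plot of association strength by phenotype and gene
#'
#' The -log10(p) profile of an [association_scan()], with dashed reference
#' lines at the two multiple-testing tiers.
#'
#' @param scan An [association_scan()] result.
#' @param gene_threshold,full_threshold Tier levels to draw.
#' @return A ggplot object.
#' @export
plot_association <- function(scan, gene_threshold = 0.017,
                             full_threshold = 0.003) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$phenotype, y = .data$neglog10p,
                                     fill = .data$gene)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = -log10(gene_threshold), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(full_threshold), linetype = 3) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)), fill = "gene") +
    ggplot2::theme_minimal()
}
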