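# Shared fixtures and independent oracle implementations used across tests.
# Oracles deliberately re-derive quantities from first principles so they
# stay independent of the package's code paths.

# Build a cohort quickly with optional planted genotype effects.
make_cohort <- function(seed, n = 164, effects = numeric(0), missing = 0,
                        a_mean = 6.33, a_sd = 2.99, snp_specs = NULL) {
  params <- cohort_params(
    n_subjects = n, seed = seed, effect_map = effects,
    missing_rate_geno = missing, a_mean = a_mean, a_sd = a_sd,
    snp_specs = snp_specs %||% default_snp_specs()
  )
  generate_cohort(params)
}

# Subject-level reconstruction of the reference root split: 110 GG
# homozygotes of which 89% are non-responders, 46 AG/AA carriers of which
# 43% are good responders (counts rounded to integers), with the single AA
# subject kept in the carrier pool.
fig_root_data <- function() {
  n_gg <- 110
  n_carrier <- 46
  gg_nr <- round(0.89 * n_gg)        # 98
  carrier_gr <- round(0.43 * n_carrier)  # 20
  data.frame(
    genotype = c(rep("GG", n_gg), "AA", rep("AG", n_carrier - 1)),
    response = c(rep(c("NR", "GR"), c(gg_nr, n_gg - gg_nr)),
                 rep(c("GR", "NR"), c(carrier_gr, n_carrier - carrier_gr)))
  )
}

# Cohort whose response is driven through the B items (complexity/adherence
# confounders), as in real Alda ratings: the best-estimate tree then splits
# and every phenotype is non-degenerate. Genotypes are drawn independently
# of the response unless `effects` shifts the latent A score per minor
# allele.
make_structured_cohort <- function(seed, n = 164, effects = numeric(0)) {
  specs <- default_snp_specs()
  geno <- sapply(seq_len(nrow(specs)), function(j) {
    sample_genotypes(specs$maf[j], n, seed = 50 * seed + j)
  })
  colnames(geno) <- specs$snp_id
  set.seed(77000 + seed)
  probs <- default_b_item_probs()
  b <- sapply(1:5, function(i) sample(0:2, n, TRUE, prob = probs[i, ]))
  latent <- 9.5 - 3.2 * b[, 5] - 0.8 * b[, 4] + rnorm(n, 0, 1.5)
  for (snp in names(effects)) {
    latent <- latent + effects[[snp]] * geno[, snp]
  }
  cohort <- tibble::tibble(
    subject_id = sprintf("S%04d", 1:n),
    a_score = as.integer(pmin(10, pmax(0, round(latent)))),
    b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], b4 = b[, 4], b5 = b[, 5],
    age = rnorm(n, 44.7, 12.3),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.6, 0.4))
  )
  genotypes <- dplyr::bind_cols(
    tibble::tibble(subject_id = cohort$subject_id),
    tibble::as_tibble(geno)
  )
  list(cohort = cohort, genotypes = genotypes,
       snp_info = specs)
}

# Simulated cohort with the two-level planted structure of the reference
# tree: a three-level genotype effect at the root (9% / interaction / 47%
# good-response rates) and, inside the heterozygote stratum only, a dominant
# second-gene effect (20% vs 43%).
fig2b_sim <- function(seed, n = 500) {
  rora <- sample_genotypes(0.5, n, seed = 10 * seed + 1)
  tim <- sample_genotypes(47 / 312, n, seed = 10 * seed + 2)
  ppar <- sample_genotypes(125 / 310, n, seed = 10 * seed + 3)
  set.seed(90000 + seed)
  p_gr <- ifelse(rora == 0, 0.09,
                 ifelse(rora == 2, 0.47,
                        ifelse(tim == 0, 0.20, 0.43)))
  data.frame(
    RORA = c("CC", "TC", "TT")[rora + 1],
    TIMELESS = c("GG", "AG", "AA")[tim + 1],
    PPARGC1A = c("GG", "AG", "AA")[ppar + 1],
    age = rnorm(n, 44.7, 12.3),
    sex = sample(c("female", "male"), n, replace = TRUE),
    y = factor(ifelse(rbinom(n, 1, p_gr) == 1, "GR", "NR"),
               levels = c("GR", "NR"))
  )
}

# Does a fitted tree show the planted topology: a three-group genotype root
# with the second gene splitting inside the heterozygote branch?
recovers_fig2b_topology <- function(fit) {
  nodes <- fit$nodes
  root <- nodes[nodes$node_id == 0, ]
  if (root$terminal || root$split_variable != "RORA") return(FALSE)
  if (length(root$groups[[1]]) != 3) return(FALSE)
  kids <- nodes[!is.na(nodes$parent_id) & nodes$parent_id == 0, ]
  het_idx <- which(vapply(root$groups[[1]],
                          function(g) identical(g, "TC"), logical(1)))
  if (!length(het_idx)) return(FALSE)
  het_child <- kids[het_idx, ]
  !het_child$terminal && het_child$split_variable == "TIMELESS"
}

# --- independent oracles ----------------------------------------------------

# Textbook Pearson chi-square via explicit loops.
oracle_chisq <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      if (e > 0) stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Two-sided Fisher p for a 2x2 table: hypergeometric sum over all tables
# with the same margins whose probability does not exceed the observed one.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  sum(probs[probs <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
}

# Exact two-sided rank-sum p via Mann-Whitney U counting (ties = 1/2) over
# every subset assignment, a formulation different from the package's
# rank-sum enumeration.
oracle_ranksum_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  u_of <- function(a, b) sum(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
  u_obs <- u_of(x1, x2)
  mu <- n1 * length(x2) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(id) u_of(pooled[id], pooled[-id]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exhaustive CHAID split-search oracle. Enumerates every assignment of the
# predictor's observed categories to groups (via brute-force label vectors,
# canonicalized), keeps contiguous assignments for ordinal predictors,
# filters on the minimum child size, scores each grouped table with the
# textbook chi-square, and multiplies by an enumeration-based Bonferroni
# count (number of admissible-by-shape partitions with that many groups,
# regardless of child-size filtering).
oracle_partition_assignments <- function(k, ordinal) {
  grids <- do.call(expand.grid, rep(list(seq_len(k)), k))
  canon <- apply(grids, 1, function(a) {
    # relabel groups by order of first appearance
    match(a, unique(a))
  })
  canon <- unique(t(canon))
  if (ordinal) {
    keep <- apply(canon, 1, function(a) all(diff(a) %in% c(0, 1)))
    canon <- canon[keep, , drop = FALSE]
  }
  canon
}

oracle_best_for_predictor <- function(x, y, ordinal, min_child) {
  levs <- unique(sort(as.character(x)))
  k <- length(levs)
  if (k < 2) return(NULL)
  asg <- oracle_partition_assignments(k, ordinal)
  r_all <- apply(asg, 1, max)
  b_count <- table(r_all)  # enumeration-based Bonferroni multiplier
  best <- NULL
  for (i in seq_len(nrow(asg))) {
    r <- r_all[i]
    if (r < 2) next
    g <- asg[i, ][match(as.character(x), levs)]
    tab <- table(g, y)
    if (any(rowSums(tab) < min_child)) next
    stat <- oracle_chisq(tab)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    p <- pchisq(stat, df, lower.tail = FALSE)
    p_adj <- min(1, p * b_count[[as.character(r)]])
    if (is.null(best) || p_adj < best$p_adj - 1e-15) {
      best <- list(p_adj = p_adj, statistic = stat, r = r)
    }
  }
  best
}
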