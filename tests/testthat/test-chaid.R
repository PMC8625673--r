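test_that("Bonferroni multipliers count category groupings", {
  expect_equal(bonferroni_multiplier(3, 2, "nominal"), 3)
  expect_equal(bonferroni_multiplier(3, 2, "ordinal"), 2)
  expect_equal(bonferroni_multiplier(4, 2, "nominal"), 7)   # S(4,2)
  expect_equal(bonferroni_multiplier(4, 3, "nominal"), 6)   # S(4,3)
  expect_equal(bonferroni_multiplier(5, 5, "nominal"), 1)
  expect_equal(bonferroni_multiplier(6, 3, "ordinal"), choose(5, 2))
  expect_error(bonferroni_multiplier(2, 3, "nominal"),
               class = "aldaphen_invalid_parameter")
  # multipliers match the enumeration the oracle performs
  for (k in 2:4) {
    asg <- oracle_partition_assignments(k, ordinal = FALSE)
    counts <- table(apply(asg, 1, max))
    for (r in 2:k) {
      expect_equal(bonferroni_multiplier(k, r, "nominal"),
                   counts[[as.character(r)]])
    }
    asg_o <- oracle_partition_assignments(k, ordinal = TRUE)
    counts_o <- table(apply(asg_o, 1, max))
    for (r in 2:k) {
      expect_equal(bonferroni_multiplier(k, r, "ordinal"),
                   counts_o[[as.character(r)]])
    }
  }
})

test_that("category merging pools homogeneous categories and keeps distinct ones", {
  # identical class distributions -> merged into one group
  x <- rep(c("a", "b"), each = 40)
  y <- rep(rep(c("GR", "NR"), 2), c(10, 30, 10, 30))
  expect_length(merge_categories(x, y, "nominal"), 1)
  # maximally different pure classes -> no merging
  x2 <- rep(c("a", "b"), each = 60)
  y2 <- rep(c("GR", "NR"), each = 60)
  expect_length(merge_categories(x2, y2, "nominal"), 2)
  # a rare genotype with the same GR rate as the heterozygotes merges into it
  x3 <- rep(c("AA", "AG", "GG"), c(10, 40, 110))
  y3 <- c(rep(c("GR", "NR"), c(4, 6)),    # AA: 40% GR
          rep(c("GR", "NR"), c(16, 24)),  # AG: 40% GR
          rep(c("GR", "NR"), c(11, 99)))  # GG: 10% GR
  groups <- merge_categories(x3, y3, "nominal")
  expect_length(groups, 2)
  merged <- groups[[which(vapply(groups, length, integer(1)) == 2)]]
  expect_setequal(merged, c("AA", "AG"))
  # single category is returned unchanged
  expect_equal(merge_categories(rep("z", 10), rep(c("GR", "NR"), 5)),
               list("z"))
})

test_that("the reconstructed root split beats noise and matches the printed statistic", {
  d <- fig_root_data()
  set.seed(88)
  d$noise <- sample(c("u", "v"), nrow(d), replace = TRUE)
  dec <- best_split(d, "response", c("genotype", "noise"),
                    types = list(genotype = "nominal", noise = "nominal"))
  expect_true(dec$split)
  expect_equal(dec$variable, "genotype")
  expect_equal(dec$statistic, 21.10167, tolerance = 1e-5)
  expect_equal(dec$multiplier, 3)  # nominal, 3 categories merged to 2
  expect_equal(dec$p_adj, 3 * 4.355483e-06, tolerance = 1e-4)
  expect_lt(dec$p_adj, 0.001)
  expect_length(dec$groups, 2)
  expect_setequal(dec$groups[[which(lengths(dec$groups) == 2)]],
                  c("AA", "AG"))
})

test_that("best_split agrees with an exhaustive partition-search oracle", {
  set.seed(505)
  settings <- chaid_settings(min_parent = 15, min_child = 3)
  mismatches <- 0L
  for (i in 1:500) {
    n <- sample(20:60, 1)
    k1 <- sample(2:4, 1)
    k2 <- sample(2:4, 1)
    t1 <- sample(c("nominal", "ordinal"), 1)
    t2 <- sample(c("nominal", "ordinal"), 1)
    d <- data.frame(
      p1 = sample(letters[1:k1], n, replace = TRUE),
      p2 = sample(letters[1:k2], n, replace = TRUE),
      y = sample(c("GR", "NR"), n, replace = TRUE, prob = c(0.4, 0.6))
    )
    if (length(unique(d$y)) < 2) next
    dec <- best_split(d, "y", c("p1", "p2"),
                      types = list(p1 = t1, p2 = t2), settings = settings)
    o1 <- oracle_best_for_predictor(d$p1, d$y, t1 == "ordinal", 3)
    o2 <- oracle_best_for_predictor(d$p2, d$y, t2 == "ordinal", 3)
    oracle_ps <- c(p1 = if (is.null(o1)) NA else o1$p_adj,
                   p2 = if (is.null(o2)) NA else o2$p_adj)
    if (all(is.na(oracle_ps))) {
      if (isTRUE(dec$split)) mismatches <- mismatches + 1L
      next
    }
    ovar <- names(oracle_ps)[which.min(oracle_ps)]
    op <- min(oracle_ps, na.rm = TRUE)
    ok <- !is.na(dec$p_adj) &&
      abs(dec$p_adj - op) < 1e-9 &&
      identical(dec$variable, ovar) &&
      identical(isTRUE(dec$split), op <= settings$alpha_split)
    if (!ok) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("under the null the split test keeps its size", {
  splits <- 0L
  for (seed in 1:100) {
    set.seed(7000 + seed)
    d <- data.frame(
      x = sample(c("aa", "ab", "bb"), 200, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2)),
      y = sample(c("GR", "NR"), 200, replace = TRUE, prob = c(0.3, 0.7))
    )
    dec <- best_split(d, "y", "x", types = list(x = "nominal"))
    if (isTRUE(dec$split)) splits <- splits + 1L
  }
  expect_lte(splits / 100, 0.05 + 0.03)
})

test_that("nodes below min_parent and depth limits do not split", {
  d <- fig_root_data()
  dec <- best_split(d[1:20, ], "response", "genotype",
                    settings = chaid_settings(min_parent = 30))
  expect_false(dec$split)
  fit1 <- chaid(fig2b_sim(1), "y",
                predictors = c("RORA", "TIMELESS", "PPARGC1A"),
                settings = chaid_settings(max_depth = 1))
  expect_lte(max(fit1$nodes$depth), 1)
})

test_that("tree growth recovers a planted two-level interaction", {
  fit <- chaid(fig2b_sim(3), "y",
               predictors = c("RORA", "TIMELESS", "PPARGC1A", "age", "sex"))
  expect_equal(fit$nodes$split_variable[fit$nodes$node_id == 0], "RORA")
  expect_true(recovers_fig2b_topology(fit))
})

test_that("pure-noise predictors almost always leave a single root node", {
  single <- 0L
  for (seed in 1:20) {
    set.seed(9100 + seed)
    d <- data.frame(
      a = sample(letters[1:3], 300, replace = TRUE),
      b = sample(letters[1:4], 300, replace = TRUE),
      y = sample(c("GR", "NR"), 300, replace = TRUE)
    )
    fit <- chaid(d, "y", predictors = c("a", "b"))
    if (nrow(fit$nodes) == 1L && fit$nodes$terminal[1]) single <- single + 1L
  }
  expect_gte(single, 16L)  # two predictors, ~5% spurious splits each
})

test_that("child sizes sum to the parent size at every split", {
  for (seed in c(1, 2, 3)) {
    fit <- chaid(fig2b_sim(seed), "y",
                 predictors = c("RORA", "TIMELESS", "PPARGC1A", "age", "sex"))
    nodes <- fit$nodes
    for (id in nodes$node_id[!nodes$terminal]) {
      kids <- nodes$n[!is.na(nodes$parent_id) & nodes$parent_id == id]
      expect_equal(sum(kids), nodes$n[nodes$node_id == id])
    }
    # adjusted p never below raw p; multiplier 1 for unmerged binary splits
    with_split <- nodes[!nodes$terminal, ]
    expect_true(all(with_split$p_adj >= with_split$p_raw - 1e-12))
  }
})

test_that("a binary predictor with no merge has multiplier 1", {
  d <- data.frame(
    x = rep(c("m", "f"), each = 60),
    y = rep(c("GR", "NR", "NR", "GR"), c(45, 15, 50, 10))
  )
  dec <- best_split(d, "y", "x")
  expect_equal(dec$multiplier, 1)
})

test_that("disabling the Bonferroni adjustment never reduces the number of splits", {
  for (seed in 1:20) {
    set.seed(8000 + seed)
    n <- 250
    x1 <- sample(c("aa", "ab", "bb"), n, replace = TRUE)
    y <- ifelse(runif(n) < ifelse(x1 == "aa", 0.45, 0.30), "GR", "NR")
    d <- data.frame(x1 = x1,
                    x2 = sample(letters[1:3], n, replace = TRUE), y = y)
    with_b <- chaid(d, "y", predictors = c("x1", "x2"),
                    settings = chaid_settings(bonferroni = TRUE))
    without_b <- chaid(d, "y", predictors = c("x1", "x2"),
                       settings = chaid_settings(bonferroni = FALSE))
    expect_gte(sum(!without_b$nodes$terminal), sum(!with_b$nodes$terminal))
  }
})

test_that("cross-validation estimates the expected risks deterministically", {
  # perfectly separable predictor: near-zero risk
  d <- data.frame(x = rep(c("a", "b"), each = 100),
                  y = rep(c("GR", "NR"), each = 100))
  cv <- cross_validate(d, "y", "x",
                       settings = chaid_settings(min_parent = 20,
                                                 min_child = 5))
  expect_lt(cv$risk, 0.05)
  # pure noise, balanced classes: risk near one half
  set.seed(92)
  d2 <- data.frame(x = sample(letters[1:3], 1000, replace = TRUE),
                   y = sample(c("GR", "NR"), 1000, replace = TRUE))
  cv2 <- cross_validate(d2, "y", "x")
  expect_lt(abs(cv2$risk - 0.5), 0.05)
  # determinism under the settings seed
  cv3 <- cross_validate(d2, "y", "x")
  expect_identical(cv2, cv3)
})

test_that("rendering reports consistent node composition", {
  fit <- chaid(fig2b_sim(5), "y",
               predictors = c("RORA", "TIMELESS", "PPARGC1A"))
  rt <- render_tree(fit)
  expect_equal(length(rt$text), nrow(fit$nodes))
  expect_match(rt$dot, "^digraph")
  expect_equal(sum(grepl("->", strsplit(rt$dot, "\n")[[1]], fixed = TRUE)),
               nrow(fit$nodes) - 1)
  # percentages inside each rendered node sum to ~100
  for (counts in fit$nodes$class_counts) {
    pct <- round(100 * counts / sum(counts))
    expect_lte(abs(sum(pct) - 100), 1)
  }
  # single-node tree renders a one-node graph
  d0 <- data.frame(x = sample(letters[1:2], 50, replace = TRUE),
                   y = sample(c("GR", "NR"), 50, replace = TRUE))
  fit0 <- chaid(d0, "y", "x", settings = chaid_settings(alpha_split = 1e-9))
  rt0 <- render_tree(fit0)
  expect_length(rt0$text, 1)
})

test_that("tidy, glance and autoplot expose the fitted tree", {
  fit <- chaid(fig2b_sim(7), "y",
               predictors = c("RORA", "TIMELESS", "PPARGC1A"))
  td <- tidy(fit)
  expect_true(all(c("node_id", "n_GR", "n_NR", "p_adj", "terminal") %in%
                    names(td)))
  expect_equal(td$n, td$n_GR + td$n_NR)
  gl <- glance(fit)
  expect_equal(gl$n_leaves, sum(td$terminal))
  expect_s3_class(autoplot(fit), "ggplot")
})
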