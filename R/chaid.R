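# CHAID (Chi-square Automatic Interaction Detection) classification trees
# for a binary target, built from scratch: per-predictor category grouping,
# Bonferroni-multiplier adjusted chi-square split selection, stopping rules
# and stratified cross-validation.

#' Settings for CHAID tree growth
#'
#' @param alpha_split Significance level a Bonferroni-adjusted split p-value
#'   must reach for the node to split. Default 0.05.
#' @param alpha_merge Level used by the greedy category-merge heuristic
#'   ([merge_categories()]): merging continues while the most similar pair of
#'   groups has p > `alpha_merge`. Default 0.05.
#' @param min_parent Minimum node size eligible for splitting. Default 30
#'   (suited to cohorts of a few hundred subjects; classic large-sample
#'   defaults are 100/50).
#' @param min_child Minimum size of every child a split may create. Default 10.
#' @param max_depth Maximum tree depth (root = depth 0). Default 3.
#' @param bonferroni Apply the Bonferroni multiplier to split p-values.
#'   Default `TRUE`.
#' @param age_bins Continuous predictors are discretized into at most this
#'   many quantile bins, treated as ordinal. Default 10.
#' @param cv_folds Folds for [cross_validate()]. Default 10.
#' @param seed Seed for fold assignment.
#' @return An object of class `chaid_settings`.
#' @export
chaid_settings <- function(alpha_split = 0.05, alpha_merge = 0.05,
                           min_parent = 30, min_child = 10, max_depth = 3,
                           bonferroni = TRUE, age_bins = 10, cv_folds = 10,
                           seed = 1L) {
  assert_scalar_number(alpha_split, "alpha_split", 1e-12, 1)
  assert_scalar_number(alpha_merge, "alpha_merge", 1e-12, 1)
  min_parent <- assert_count(min_parent, "min_parent")
  min_child <- assert_count(min_child, "min_child")
  max_depth <- assert_count(max_depth, "max_depth")
  age_bins <- assert_count(age_bins, "age_bins", lower = 2L)
  cv_folds <- assert_count(cv_folds, "cv_folds", lower = 2L)
  if (min_child > min_parent) {
    abort("`min_child` must not exceed `min_parent`.",
          class = "aldaphen_invalid_parameter")
  }
  structure(
    list(alpha_split = alpha_split, alpha_merge = alpha_merge,
         min_parent = min_parent, min_child = min_child,
         max_depth = max_depth, bonferroni = isTRUE(bonferroni),
         age_bins = age_bins, cv_folds = cv_folds,
         seed = assert_count(seed, "seed", lower = 0L)),
    class = "chaid_settings"
  )
}

# Pearson chi-square on a groups x classes table; empty rows are dropped.
# Degenerate tables (one non-empty row or column) score 0 with p = 1.
chaid_chisq <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || sum(colSums(tab) > 0) < 2L) {
    return(list(statistic = 0, df = 0L, p = 1))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  keep <- expected > 0
  stat <- sum((tab[keep] - expected[keep])^2 / expected[keep])
  df <- (nrow(tab) - 1L) * (sum(colSums(tab) > 0) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# Stirling number of the second kind, S(n, k).
stirling2 <- function(n, k) {
  if (k > n) return(0)
  if (k == 0) return(as.numeric(n == 0))
  i <- 0:k
  round(sum((-1)^i * choose(k, i) * (k - i)^n) / factorial(k))
}

#' CHAID Bonferroni multiplier
#'
#' Number of distinct ways `n_categories` predictor categories can be reduced
#' to `n_groups` groups: the Stirling number of the second kind for nominal
#' predictors, and the number of adjacent cut placements
#' `choose(n_categories - 1, n_groups - 1)` for ordinal predictors. The split
#' p-value is multiplied by this count (and capped at 1) to account for the
#' grouping search within the predictor.
#'
#' @param n_categories Number of original categories (c).
#' @param n_groups Number of merged groups (r), `1 <= r <= c`.
#' @param type `"nominal"` or `"ordinal"`.
#' @return A single number, the multiplier B.
#' @export
#' @examples
#' bonferroni_multiplier(3, 2, "nominal") # 3
#' bonferroni_multiplier(3, 2, "ordinal") # 2
bonferroni_multiplier <- function(n_categories, n_groups,
                                  type = c("nominal", "ordinal")) {
  type <- match.arg(type)
  n_categories <- assert_count(n_categories, "n_categories")
  n_groups <- assert_count(n_groups, "n_groups")
  if (n_groups > n_categories) {
    abort("`n_groups` cannot exceed `n_categories`.",
          class = "aldaphen_invalid_parameter")
  }
  if (type == "ordinal") choose(n_categories - 1, n_groups - 1)
  else stirling2(n_categories, n_groups)
}

# All assignments of k categories to groups.
# Ordinal: contiguous blocks (cut placements); nominal: set partitions via
# restricted-growth strings. Each element is an integer vector `assign` of
# length k with group indices 1..r.
ordinal_assignments <- function(k) {
  out <- list()
  for (r in seq_len(k)) {
    cuts <- if (r == 1) list(integer(0)) else combn(k - 1, r - 1, simplify = FALSE)
    for (cut in cuts) {
      out[[length(out) + 1L]] <- rep(seq_len(r), diff(c(0L, cut, k)))
    }
  }
  out
}

nominal_assignments <- function(k) {
  out <- list()
  recurse <- function(assign, m) {
    i <- length(assign) + 1L
    if (i > k) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (g in seq_len(min(m + 1L, i))) recurse(c(assign, g), max(m, g))
  }
  recurse(integer(0), 0L)
  out
}

# Greedy Kass-style category merging used by merge_categories() and as the
# search fallback for high-cardinality nominal predictors.
greedy_groups <- function(x, y, type, alpha_merge) {
  levs <- levels(x)[tabulate(x, nbins = nlevels(x)) > 0]
  groups <- as.list(levs)
  if (type == "ordinal") groups <- groups[order(match(levs, levels(x)))]
  repeat {
    k <- length(groups)
    if (k < 2L) break
    pairs <- if (type == "ordinal") {
      lapply(seq_len(k - 1L), function(i) c(i, i + 1L))
    } else {
      combn(k, 2L, simplify = FALSE)
    }
    ps <- vapply(pairs, function(pr) {
      sel1 <- x %in% groups[[pr[1]]]
      sel2 <- x %in% groups[[pr[2]]]
      tab <- rbind(table(y[sel1]), table(y[sel2]))
      chaid_chisq(tab)$p
    }, numeric(1))
    if (max(ps) <= alpha_merge) break
    pr <- pairs[[which.max(ps)]]
    groups[[pr[1]]] <- c(groups[[pr[1]]], groups[[pr[2]]])
    groups <- groups[-pr[2]]
    if (type == "ordinal") {
      groups <- groups[order(vapply(groups, function(g) min(match(g, levels(x))),
                                    numeric(1)))]
    }
  }
  groups
}

#' Merge predictor categories that are homogeneous in the target
#'
#' Classic greedy CHAID merge step: repeatedly pools the pair of category
#' groups (any pair for nominal predictors, adjacent pairs for ordinal ones)
#' whose 2-by-classes sub-table has the *largest* chi-square p-value, as long
#' as that p-value exceeds `alpha_merge`; stops when all remaining pairwise
#' p-values are at or below `alpha_merge`. Categories indistinguishable from
#' each other throughout can therefore collapse into a single group, in
#' which case the predictor offers no split.
#'
#' @param x Predictor values (factor or vector; empty categories are dropped).
#' @param y Target labels (factor or vector).
#' @param type `"nominal"` or `"ordinal"` (merge adjacency).
#' @param alpha_merge Merge significance level; default 0.05.
#' @return A list of character vectors, each one merged group of category
#'   levels. A single-category predictor is returned unchanged.
#' @export
#' @examples
#' x <- rep(c("AA", "AG", "GG"), c(10, 40, 50))
#' y <- rep(rep(c("GR", "NR"), 3), c(4, 6, 16, 24, 5, 45))
#' merge_categories(x, y, type = "nominal")
merge_categories <- function(x, y, type = c("nominal", "ordinal"),
                             alpha_merge = 0.05) {
  type <- match.arg(type)
  x <- if (is.factor(x)) droplevels(x) else factor(x)
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.",
          class = "aldaphen_consistency_error")
  }
  if (nlevels(x) < 2L) return(list(levels(x)))
  greedy_groups(x, y, type, alpha_merge)
}

# Evaluate one predictor at a node: search admissible groupings and return
# the one minimizing the Bonferroni-adjusted chi-square p-value.
# x: factor (node subset); y: factor target; returns NULL if no admissible split.
evaluate_predictor <- function(x, y, type, settings) {
  present <- levels(x)[tabulate(x, nbins = nlevels(x)) > 0]
  k <- length(present)
  if (k < 2L) return(NULL)
  xi <- factor(as.character(x), levels = present)
  counts <- table(xi, y)

  assignments <- if (type == "ordinal") {
    ordinal_assignments(k)
  } else if (k <= 6L) {
    nominal_assignments(k)
  } else {
    # cardinality too high for exhaustive set-partition search: fall back to
    # the greedy merge heuristic and evaluate its grouping only
    groups <- greedy_groups(xi, y, type, settings$alpha_merge)
    list(vapply(present, function(lv) {
      which(vapply(groups, function(g) lv %in% g, logical(1)))
    }, integer(1)))
  }

  best <- NULL
  for (assign in assignments) {
    r <- max(assign)
    if (r < 2L) next
    grouped <- rowsum(counts, group = assign, reorder = TRUE)
    if (any(rowSums(grouped) < settings$min_child)) next
    res <- chaid_chisq(grouped)
    mult <- if (settings$bonferroni) bonferroni_multiplier(k, r, type) else 1
    p_adj <- min(1, res$p * mult)
    if (is.null(best) || p_adj < best$p_adj - 1e-15) {
      best <- list(groups = split(present, assign), n_groups = r,
                   statistic = res$statistic, df = res$df, p_raw = res$p,
                   multiplier = mult, p_adj = p_adj, n_categories = k)
    }
  }
  best
}

#' Select the best CHAID split for a node
#'
#' For each candidate predictor, searches the admissible category groupings
#' (all contiguous groupings for ordinal predictors; all set partitions for
#' nominal predictors with up to 6 categories, the greedy
#' [merge_categories()] grouping beyond that), computes the Pearson
#' chi-square of the grouped groups-by-classes table, and adjusts its p-value
#' by the [bonferroni_multiplier()]. Groupings creating a child smaller than
#' `min_child` are inadmissible. The predictor with the smallest adjusted
#' p-value wins (ties broken by predictor name); the node splits only when
#' that p-value is at most `alpha_split` and the node has at least
#' `min_parent` rows.
#'
#' @param data Data frame containing the target and predictor columns.
#' @param target Name of the binary target column.
#' @param predictors Character vector of predictor column names.
#' @param types Named character vector (`"nominal"`/`"ordinal"`) per
#'   predictor; defaults are guessed by [chaid()]'s rules.
#' @param settings A [chaid_settings()] object.
#' @return A list with `split` (logical) and, when a candidate exists,
#'   `variable`, `groups` (list of category-level vectors), `statistic`,
#'   `df`, `p_raw`, `multiplier`, `p_adj`.
#' @export
best_split <- function(data, target, predictors, types = NULL,
                       settings = chaid_settings()) {
  y <- droplevels(factor(data[[target]]))
  prep <- prepare_predictors(data, predictors, types, settings)
  decide_split(prep$frame, y, predictors, prep$types, settings)
}

decide_split <- function(pframe, y, predictors, types, settings) {
  none <- list(split = FALSE, variable = NA_character_, p_adj = NA_real_)
  if (length(y) < settings$min_parent || nlevels(y) < 2L) return(none)
  cands <- list()
  for (v in sort(predictors)) {
    fit <- evaluate_predictor(droplevels(pframe[[v]]), y, types[[v]], settings)
    if (!is.null(fit)) cands[[v]] <- fit
  }
  if (!length(cands)) return(none)
  p_adjs <- vapply(cands, `[[`, numeric(1), "p_adj")
  v <- names(cands)[which.min(p_adjs)]  # ties: first in sorted name order
  best <- cands[[v]]
  c(list(split = best$p_adj <= settings$alpha_split, variable = v), best)
}

# Predictor preparation: continuous columns (> age_bins distinct values) are
# quantile-binned and treated as ordinal; low-cardinality numeric columns
# become ordinal factors of their values; characters/factors are nominal
# unless ordered. Missing values form their own "(missing)" category and the
# predictor is then handled as nominal.
prepare_predictors <- function(data, predictors, types, settings) {
  frame <- list()
  out_types <- list()
  breaks <- list()
  for (v in predictors) {
    x <- data[[v]]
    declared <- if (!is.null(types) && v %in% names(types)) types[[v]] else NULL
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > settings$age_bins) {
      qs <- unique(quantile(x, probs = seq(0, 1, length.out = settings$age_bins + 1),
                            na.rm = TRUE, names = FALSE))
      br <- qs[-c(1, length(qs))]
      breaks[[v]] <- br
      x <- bin_numeric(x, br)
      type <- declared %||% "ordinal"
    } else if (is.numeric(x)) {
      x <- factor(x, levels = sort(unique(x[!is.na(x)])))
      type <- declared %||% "ordinal"
    } else if (is.ordered(x)) {
      x <- factor(as.character(x), levels = levels(x))
      type <- declared %||% "ordinal"
    } else {
      x <- factor(x)
      type <- declared %||% "nominal"
    }
    if (anyNA(x)) {
      x <- factor(ifelse(is.na(as.character(x)), "(missing)", as.character(x)),
                  levels = c(levels(x), "(missing)"))
      type <- "nominal"
    }
    frame[[v]] <- x
    out_types[[v]] <- type
  }
  list(frame = frame, types = out_types, breaks = breaks)
}

bin_numeric <- function(x, br) {
  labels <- bin_labels(br)
  idx <- findInterval(x, br, left.open = FALSE) + 1L
  factor(labels[idx], levels = labels)
}

bin_labels <- function(br) {
  lo <- c("-Inf", format(br, digits = 4, trim = TRUE))
  hi <- c(format(br, digits = 4, trim = TRUE), "Inf")
  paste0("(", lo, ",", hi, "]")
}

#' Fit a CHAID classification tree
#'
#' Grows a binary-target CHAID tree by recursively applying [best_split()]
#' until no candidate split reaches `alpha_split`, a node falls below
#' `min_parent`, is pure, or `max_depth` is reached. Nodes are numbered
#' breadth-first (root = 0). Continuous predictors are quantile-binned
#' ordinals; missing predictor values form their own category.
#'
#' @inheritParams best_split
#' @param data Data frame with the target and predictor columns.
#' @param target Name of the binary target column (first factor level is
#'   treated as the positive class; a `GR`/`NR` factor puts GR first).
#' @param predictors Predictor column names; default: all other columns.
#' @return An object of class `chaid_tree` with a breadth-first `nodes`
#'   tibble (sizes, class counts and percentages, split statistics) and the
#'   preparation metadata needed to route new observations.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_params(seed = 3))
#' d <- sim$cohort
#' d$resp <- alda_category(total_score(d$a_score, d$b1 + d$b2 + d$b3 + d$b4 + d$b5))
#' fit <- chaid(d, "resp", predictors = paste0("b", 1:5))
#' fit
chaid <- function(data, target, predictors = NULL, types = NULL,
                  settings = chaid_settings()) {
  data <- as.data.frame(data)
  if (!target %in% names(data)) {
    abort(sprintf("target column `%s` not found.", target),
          class = "aldaphen_configuration_error")
  }
  predictors <- predictors %||% setdiff(names(data), target)
  missing_preds <- setdiff(predictors, names(data))
  if (length(missing_preds)) {
    abort(paste("predictor columns not found:",
                paste(missing_preds, collapse = ", ")),
          class = "aldaphen_configuration_error")
  }
  y <- factor(data[[target]])
  if (anyNA(y)) abort("target labels must not be missing.",
                      class = "aldaphen_invalid_parameter")
  if (nlevels(droplevels(y)) > 2L) {
    abort("chaid() supports binary targets only.",
          class = "aldaphen_invalid_parameter")
  }
  classes <- levels(y)
  prep <- prepare_predictors(data, predictors, types, settings)

  nodes <- list()
  # queue entries: rows index, parent id, depth
  queue <- list(list(rows = seq_along(y), parent = NA_integer_, depth = 0L))
  next_id <- 0L
  memberships <- list()
  while (length(queue)) {
    item <- queue[[1]]
    queue <- queue[-1]
    id <- next_id
    next_id <- next_id + 1L
    rows <- item$rows
    yv <- y[rows]
    counts <- as.integer(table(yv))
    node <- list(
      node_id = id, parent_id = item$parent, depth = item$depth,
      n = length(rows), class_counts = list(setNames(counts, classes)),
      split_variable = NA_character_, groups = list(NULL),
      statistic = NA_real_, df = NA_integer_, p_raw = NA_real_,
      multiplier = NA_real_, p_adj = NA_real_, terminal = TRUE
    )
    can_split <- item$depth < settings$max_depth &&
      length(rows) >= settings$min_parent &&
      all(counts > 0L) && nlevels(droplevels(yv)) == 2L
    if (can_split) {
      sub <- lapply(prep$frame, function(col) droplevels(col[rows]))
      dec <- decide_split(sub, droplevels(yv), predictors, prep$types, settings)
      if (isTRUE(dec$split)) {
        node$split_variable <- dec$variable
        node$groups <- list(dec$groups)
        node$statistic <- dec$statistic
        node$df <- as.integer(dec$df)
        node$p_raw <- dec$p_raw
        node$multiplier <- dec$multiplier
        node$p_adj <- dec$p_adj
        node$terminal <- FALSE
        xv <- as.character(prep$frame[[dec$variable]][rows])
        for (g in dec$groups) {
          queue[[length(queue) + 1L]] <- list(
            rows = rows[xv %in% g], parent = id, depth = item$depth + 1L
          )
        }
      }
    }
    nodes[[id + 1L]] <- node
    memberships[[id + 1L]] <- rows
  }

  nodes_tbl <- dplyr::bind_rows(lapply(nodes, as_tibble))
  structure(
    list(nodes = nodes_tbl, target = target, classes = classes,
         predictors = predictors, types = prep$types, breaks = prep$breaks,
         settings = settings, n = length(y),
         memberships = memberships),
    class = "chaid_tree"
  )
}

#' Route observations through a fitted CHAID tree
#'
#' @param object A [chaid()] tree.
#' @param newdata Data frame with the tree's predictor columns.
#' @param type `"prob"` (probability of the positive class, i.e. the leaf
#'   fraction of the first target level), `"class"` (leaf majority class) or
#'   `"node"` (leaf node id).
#' @param unseen How to route a category that belongs to no child group at a
#'   split: `"error"` (default; fail loudly) or `"majority"` (follow the
#'   largest child, used by [cross_validate()]).
#' @param ... Unused.
#' @return Numeric, factor or integer vector, one element per row.
#' @export
predict.chaid_tree <- function(object, newdata,
                               type = c("prob", "class", "node"),
                               unseen = c("error", "majority"), ...) {
  type <- match.arg(type)
  unseen <- match.arg(unseen)
  newdata <- as.data.frame(newdata)
  nodes <- object$nodes
  # prepare predictor columns with the training binning
  cols <- list()
  for (v in object$predictors) {
    x <- newdata[[v]]
    if (!is.null(object$breaks[[v]])) {
      x <- as.character(bin_numeric(as.numeric(x), object$breaks[[v]]))
    } else {
      x <- as.character(x)
    }
    x[is.na(x)] <- "(missing)"
    cols[[v]] <- x
  }
  node_of <- integer(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    id <- 0L
    repeat {
      row <- nodes[nodes$node_id == id, ]
      if (isTRUE(row$terminal)) break
      v <- row$split_variable
      groups <- row$groups[[1]]
      val <- cols[[v]][i]
      hit <- which(vapply(groups, function(g) val %in% g, logical(1)))
      kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == id]
      if (!length(hit)) {
        if (unseen == "error") {
          abort(sprintf("cannot route row %d: category '%s' of `%s` matches no child group.",
                        i, val, v),
                class = "aldaphen_routing_error")
        }
        hit <- which.max(nodes$n[match(kids, nodes$node_id)])
      }
      id <- kids[hit]
    }
    node_of[i] <- id
  }
  if (type == "node") return(node_of)
  counts <- nodes$class_counts[match(node_of, nodes$node_id)]
  if (type == "prob") {
    return(vapply(counts, function(cc) cc[[1]] / sum(cc), numeric(1)))
  }
  factor(vapply(counts, function(cc) object$classes[which.max(cc)], character(1)),
         levels = object$classes)
}

#' Cross-validated misclassification risk of a CHAID tree
#'
#' Stratified k-fold cross-validation: the tree is refitted on each training
#' partition and the held-out subjects are classified by their leaf's
#' majority class. Folds are stratified by the target and drawn from the
#' settings seed; a training fold missing one of the two classes triggers a
#' re-draw with a warning. Held-out categories absent from the refitted tree
#' are routed to the largest child.
#'
#' @inheritParams chaid
#' @return A tibble with `risk` (misclassification proportion), `se` (its
#'   binomial standard error) and `folds`.
#' @export
cross_validate <- function(data, target, predictors = NULL, types = NULL,
                           settings = chaid_settings()) {
  data <- as.data.frame(data)
  predictors <- predictors %||% setdiff(names(data), target)
  y <- factor(data[[target]])
  n <- nrow(data)
  k <- min(settings$cv_folds, n)
  draw_folds <- function(shift) {
    folds <- integer(n)
    with_substream(settings$seed + shift, "cv_folds", {
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    folds
  }
  folds <- draw_folds(0L)
  attempt <- 0L
  while (nlevels(droplevels(y)) >= 2L && attempt < 5L &&
         any(vapply(seq_len(k), function(f) {
           nlevels(droplevels(y[folds != f])) < 2L
         }, logical(1)))) {
    attempt <- attempt + 1L
    warn("a training fold lost one target class; re-drawing folds.")
    folds <- draw_folds(attempt)
  }
  wrong <- logical(n)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    fit <- chaid(train, target, predictors, types, settings)
    pred <- predict(fit, test, type = "class", unseen = "majority")
    wrong[folds == f] <- as.character(pred) != as.character(y[folds == f])
  }
  risk <- mean(wrong)
  tibble(risk = risk, se = sqrt(risk * (1 - risk) / n), folds = k)
}
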