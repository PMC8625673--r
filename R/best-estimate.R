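#' Fit the best-estimate (Algo) response model
#'
#' Trains a CHAID tree (see [chaid()]) on the five B-scale confounder items
#' to reproduce, de novo, the tree-derived "best estimate" of lithium
#' response. The provisional training label is a good A-scale response
#' (`a_score >= label_cutoff`, default 7); each leaf then stores the fraction
#' of good responders among its training subjects, which is the GR
#' probability (GRp) assigned to any subject routed to that leaf. The
#' categorical best-estimate phenotype (Algo) calls GR when GRp strictly
#' exceeds `grp_threshold` (default 0.62).
#'
#' B items are entered as ordinal predictors (scores 0 < 1 < 2).
#'
#' @param cohort Cohort tibble with `a_score` and `b1`..`b5` columns; at
#'   least 40 rows with non-degenerate B-item variation are recommended.
#' @param settings [chaid_settings()] controlling tree growth.
#' @param grp_threshold Strict GR cutoff on the leaf probability.
#' @param label_cutoff Provisional-label boundary on the A score.
#' @return An object of class `best_estimate` wrapping the fitted tree, the
#'   threshold and the training-label rule.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_params(seed = 11))
#' model <- fit_best_estimate(sim$cohort)
#' head(grp(model, sim$cohort))
fit_best_estimate <- function(cohort, settings = chaid_settings(),
                              grp_threshold = 0.62, label_cutoff = 7) {
  cohort <- as_tibble(cohort)
  needed <- c("a_score", paste0("b", 1:5))
  if (!all(needed %in% names(cohort))) {
    abort("`cohort` needs columns a_score and b1..b5.",
          class = "aldaphen_configuration_error")
  }
  assert_proportion(grp_threshold, "grp_threshold")
  label <- factor(ifelse(cohort$a_score >= label_cutoff, "GR", "NR"),
                  levels = c("GR", "NR"))
  if (nlevels(droplevels(label)) < 2L) {
    abort("provisional response label is degenerate (single class); cannot fit a tree.",
          class = "aldaphen_no_tree_error")
  }
  train <- dplyr::mutate(cohort[paste0("b", 1:5)], .label = label)
  tree <- chaid(train, ".label", predictors = paste0("b", 1:5),
                types = setNames(rep("ordinal", 5), paste0("b", 1:5)),
                settings = settings)
  structure(
    list(tree = tree, grp_threshold = grp_threshold,
         label_rule = sprintf("GR iff a_score >= %g", label_cutoff),
         settings = settings),
    class = "best_estimate"
  )
}

#' Good-response probability from a best-estimate model
#'
#' Routes each subject down the fitted tree and returns the GR fraction of
#' the destination leaf. Subjects with a B-item category that cannot be
#' routed raise an error rather than being silently imputed.
#'
#' @param model A [fit_best_estimate()] model.
#' @param cohort Tibble with `b1`..`b5` columns (all items observed).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
grp <- function(model, cohort) {
  stopifnot(inherits(model, "best_estimate"))
  cohort <- as_tibble(cohort)
  if (anyNA(cohort[paste0("b", 1:5)])) {
    abort("all B items must be observed to compute GRp.",
          class = "aldaphen_routing_error")
  }
  predict(model$tree, cohort, type = "prob")
}

#' @export
print.best_estimate <- function(x, ...) {
  cat(sprintf("Best-estimate lithium-response model (training label: %s; GR iff GRp > %.2f)\n",
              x$label_rule, x$grp_threshold))
  print(x$tree)
  invisible(x)
}

#' @describeIn fit_best_estimate Node table of the underlying tree.
#' @param x,object A `best_estimate` model.
#' @param ... Unused.
#' @method tidy best_estimate
#' @export
tidy.best_estimate <- function(x, ...) tidy(x$tree)

#' @describeIn fit_best_estimate One-row summary including the number of
#'   distinct GRp values (leaves).
#' @method glance best_estimate
#' @export
glance.best_estimate <- function(x, ...) {
  dplyr::mutate(glance(x$tree), grp_threshold = x$grp_threshold)
}
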