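#' Alda Total Score
#'
#' The Total Score (TS) is the A-scale score minus the summed B-scale score,
#' floored at zero: when the confounder total exceeds the benefit rating the
#' response is reported as 0.
#'
#' @param a_score Integer vector, A-scale score(s) in 0-10.
#' @param b_total Integer vector, summed B items in 0-10.
#' @return Integer vector of Total Scores in 0-10.
#' @export
#' @examples
#' total_score(8, 2)  # 6
#' total_score(3, 5)  # 0 (floor rule)
total_score <- function(a_score, b_total) {
  check_ratings(a_score, b_total)
  as.integer(pmax(0L, a_score - b_total))
}

check_ratings <- function(a_score, b_total) {
  if (any(is.na(a_score)) || any(a_score < 0 | a_score > 10) ||
      any(a_score != floor(a_score))) {
    abort("`a_score` must be integers in 0-10.", class = "aldaphen_invalid_rating")
  }
  if (any(is.na(b_total)) || any(b_total < 0 | b_total > 10) ||
      any(b_total != floor(b_total))) {
    abort("`b_total` must be integers in 0-10.", class = "aldaphen_invalid_rating")
  }
  invisible(NULL)
}

#' Dichotomize the Total Score into response categories
#'
#' Good responders (GR) have TS >= 7; all others are non-responders (NR).
#'
#' @param ts Integer vector of Total Scores (0-10).
#' @param cutoff Category boundary; GR iff `ts >= cutoff`. Default 7.
#' @return Factor with levels `GR`, `NR`.
#' @export
#' @examples
#' alda_category(c(7, 6))  # GR, NR
alda_category <- function(ts, cutoff = 7) {
  if (any(is.na(ts)) || any(ts < 0 | ts > 10)) {
    abort("`ts` must lie in 0-10.", class = "aldaphen_invalid_rating")
  }
  factor(ifelse(ts >= cutoff, "GR", "NR"), levels = c("GR", "NR"))
}

#' A-score phenotype restricted to low-B subjects
#'
#' Returns the A-scale score for subjects whose summed B score is below
#' `b_cutoff` (default 4) and `NA` for the excluded high-B subjects, whose
#' ratings are considered unreliable.
#'
#' @inheritParams total_score
#' @param b_cutoff Exclusion boundary; subjects with `b_total >= b_cutoff`
#'   are excluded.
#' @return Integer vector: the A score, or `NA` when excluded.
#' @export
#' @examples
#' a_low_b(c(9, 9), c(3, 4))  # 9, NA
a_low_b <- function(a_score, b_total, b_cutoff = 4) {
  check_ratings(a_score, b_total)
  ifelse(b_total < b_cutoff, as.integer(a_score), NA_integer_)
}

#' Dichotomize a good-response probability
#'
#' The best-estimate category is GR when the tree-derived probability of good
#' response strictly exceeds the threshold (default 0.62).
#'
#' @param grp_value Numeric vector of probabilities in \[0, 1\].
#' @param threshold Strict cutoff; GR iff `grp_value > threshold`.
#' @return Factor with levels `GR`, `NR`.
#' @export
#' @examples
#' algo_category(c(0.63, 0.62))  # GR, NR (strict inequality)
algo_category <- function(grp_value, threshold = 0.62) {
  if (any(is.na(grp_value)) || any(grp_value < 0 | grp_value > 1)) {
    abort("`grp_value` must lie in [0, 1].", class = "aldaphen_invalid_parameter")
  }
  assert_scalar_number(threshold, "threshold", 0, 1)
  factor(ifelse(grp_value > threshold, "GR", "NR"), levels = c("GR", "NR"))
}

#' Derive all five response phenotypes for a cohort
#'
#' Computes, for every subject: the Total Score (`ts`), the original response
#' category (`alda_cat`, GR iff TS >= 7), the low-B-restricted A score
#' (`a_low_b`, `NA` when the summed B score is >= 4), the best-estimate
#' probability of good response (`grp`, from the fitted tree model) and the
#' best-estimate category (`algo_cat`, GR iff `grp` strictly exceeds the
#' threshold).
#'
#' @param cohort Cohort tibble with `subject_id`, `a_score`, `b1`..`b5`.
#' @param model A [fit_best_estimate()] model.
#' @param grp_threshold Strict GR cutoff on `grp`; defaults to the threshold
#'   stored in `model`.
#' @return Tibble with one row per subject: `subject_id`, `ts`, `alda_cat`,
#'   `a_low_b`, `algo_cat`, `grp`, plus `b_total`.
#' @export
phenotype_table <- function(cohort, model, grp_threshold = NULL) {
  cohort <- as_tibble(cohort)
  b_total <- cohort$b1 + cohort$b2 + cohort$b3 + cohort$b4 + cohort$b5
  grp_threshold <- grp_threshold %||% model$grp_threshold
  ts <- total_score(cohort$a_score, b_total)
  p_gr <- grp(model, cohort)
  tibble(
    subject_id = cohort$subject_id,
    b_total = as.integer(b_total),
    ts = ts,
    alda_cat = alda_category(ts),
    a_low_b = a_low_b(cohort$a_score, b_total),
    grp = p_gr,
    algo_cat = algo_category(p_gr, grp_threshold)
  )
}
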