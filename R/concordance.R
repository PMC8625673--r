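#' Confusion summary against a gold standard
#'
#' Cross-tabulates predicted against gold-standard binary labels (positive
#' class = GR by default; the gold rating is the reference, so a false
#' positive is a case called GR by the new classifier but not by the
#' original rating) and derives the positive and negative predictive values,
#' overall accuracy and discordance (= 1 - accuracy).
#'
#' Predictive values with a zero denominator (no predicted positives or no
#' predicted negatives) are reported as `NA`, never coerced to 0 or 1.
#'
#' @param gold,predicted Vectors (factor/character) of equal length with the
#'   same two labels.
#' @param positive Positive-class label. Default `"GR"`.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `n`, `ppv`, `npv`,
#'   `accuracy`, `discordance`.
#' @export
#' @examples
#' confusion(rep(c("GR", "NR"), c(38, 125)),
#'           rep(c("GR", "NR", "GR", "NR"), c(30, 8, 5, 120)))
confusion <- function(gold, predicted, positive = "GR") {
  if (length(gold) != length(predicted) || !length(gold)) {
    abort("`gold` and `predicted` must be non-empty and of equal length.",
          class = "aldaphen_consistency_error")
  }
  gold_pos <- as.character(gold) == positive
  pred_pos <- as.character(predicted) == positive
  tp <- sum(pred_pos & gold_pos)
  fp <- sum(pred_pos & !gold_pos)
  fn <- sum(!pred_pos & gold_pos)
  tn <- sum(!pred_pos & !gold_pos)
  n <- tp + fp + fn + tn
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  acc <- (tp + tn) / n
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
         ppv = ppv, npv = npv, accuracy = acc, discordance = 1 - acc)
}

#' Agreement between original and best-estimate phenotypes
#'
#' Performs the three phenotype comparisons, always treating the original
#' rating as the gold standard:
#' 1. `alda_vs_algo`: original category vs best-estimate category;
#' 2. `ts_vs_grp`: Total Score dichotomized at `ts_cutoff` (>= 7 = GR) vs
#'    GRp dichotomized strictly at `grp_threshold`;
#' 3. `alowb_vs_grp`: restricted to the low-B subsample (`a_low_b`
#'    observed), the A score dichotomized at `ts_cutoff` vs dichotomized GRp.
#'
#' The continuous measures are dichotomized at their published cutoffs
#' because predictive values require binary classes. By construction the
#' gold labels of comparisons 1 and 2 coincide.
#'
#' @param phenotypes A [phenotype_table()] tibble.
#' @param grp_threshold Strict GR cutoff for GRp. Default 0.62.
#' @param ts_cutoff GR cutoff for TS / A scores. Default 7.
#' @return A tibble with one row per comparison (`comparison`, `n`, counts
#'   and the four agreement metrics). An empty low-B subsample drops the
#'   third row with a warning.
#' @export
compare_phenotype_pairs <- function(phenotypes, grp_threshold = 0.62,
                                    ts_cutoff = 7) {
  ph <- as_tibble(phenotypes)
  grp_cat <- algo_category(ph$grp, grp_threshold)
  out <- list(
    dplyr::mutate(confusion(ph$alda_cat, ph$algo_cat),
                  comparison = "alda_vs_algo", .before = 1),
    dplyr::mutate(confusion(alda_category(ph$ts, ts_cutoff), grp_cat),
                  comparison = "ts_vs_grp", .before = 1)
  )
  low_b <- !is.na(ph$a_low_b)
  if (any(low_b)) {
    out[[3]] <- dplyr::mutate(
      confusion(alda_category(ph$a_low_b[low_b], ts_cutoff), grp_cat[low_b]),
      comparison = "alowb_vs_grp", .before = 1
    )
  } else {
    warn("low-B subsample is empty; skipping the A/Low B comparison.")
  }
  dplyr::bind_rows(out)
}
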