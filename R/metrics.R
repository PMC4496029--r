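# Classification metrics used as tuning criteria.

#' F-score (harmonic mean of precision and recall)
#'
#' `2pr/(p+r)`, defined as 0 when `p + r = 0`. Vectorized.
#'
#' @param p precision in `[0, 1]`.
#' @param r recall (sensitivity) in `[0, 1]`.
#' @return F-score in `[0, 1]`.
#' @export
f_score <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  s <- p + r
  ifelse(s > 0, 2 * p * r / s, 0)
}

#' Positive-unlabeled tuning criterion r^2 / P[f(x) = 1]
#'
#' The unsupervised criterion for tuning a detector without labeled
#' negatives: squared recall on the labeled focal samples divided by the
#' fraction of *all* samples (focal plus unlabeled) assigned to the focal
#' class. Large when recall is high and the assignment is parsimonious;
#' behaves like the F-score without requiring precision. Defined as 0 when
#' the assignment fraction is 0 (recall is then necessarily 0). Vectorized.
#'
#' @param r recall on the focal class, in `[0, 1]`.
#' @param assign_fraction fraction of all samples assigned focal, in `[0, 1]`.
#' @return nonnegative criterion value.
#' @export
biased_criterion <- function(r, assign_fraction) {
  stopifnot(all(r >= 0 & r <= 1),
            all(assign_fraction >= 0 & assign_fraction <= 1))
  ifelse(assign_fraction > 0, r^2 / assign_fraction, 0)
}

# Confusion counts -> precision/recall/specificity for the focal class.
binary_metrics <- function(truth_focal, pred_focal) {
  tp <- sum(truth_focal & pred_focal)
  fp <- sum(!truth_focal & pred_focal)
  fn <- sum(truth_focal & !pred_focal)
  tn <- sum(!truth_focal & !pred_focal)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  list(precision = p, recall = r, specificity = sp, f_score = f_score(p, r))
}
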