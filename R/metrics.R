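# Evaluation metrics. AUPRC is computed as average precision (step-wise
# precision-recall sum over score thresholds, no linear interpolation), so a
# constant-score classifier attains exactly the positive prevalence. AUROC
# uses the Mann-Whitney rank statistic, which handles ties exactly.

#' Regression metrics
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @return Named list with `RMSE`, `MAE` and `R2`
#'   (\eqn{R^2 = 1 - SS_{res}/SS_{tot}}). With constant `y` the `R2` is
#'   undefined and returned as `NA` with a warning; the error metrics are
#'   still returned.
#' @export
regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  rmse <- sqrt(mean((y - y_hat)^2))
  mae <- mean(abs(y - y_hat))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant observed values: R2 is undefined")
    NA_real_
  } else 1 - sum((y - y_hat)^2) / ss_tot
  list(RMSE = rmse, MAE = mae, R2 = r2)
}

# Average precision over score thresholds (ties handled as blocks).
average_precision <- function(y, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  n_pos <- sum(y == 1)
  # threshold at each distinct score value
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

# Mann-Whitney AUROC (midranks, exact under ties).
rank_auroc <- function(y, scores) {
  r <- rank(scores)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics
#'
#' Threshold-free areas plus point precision/recall at a 0.5 threshold.
#' AUPRC is average precision, whose no-skill baseline equals the positive
#' prevalence; AUROC is the rank (Mann-Whitney) statistic.
#'
#' @param y 0/1 labels (both classes present).
#' @param scores Predicted scores or probabilities for class 1.
#' @param threshold Decision threshold for the point metrics (default 0.5).
#' @return Named list with `AUROC`, `AUPRC`, `precision`, `recall`.
#' @export
classification_metrics <- function(y, scores, threshold = 0.5) {
  y <- as.integer(y)
  stopifnot(length(y) == length(scores), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) {
    stop(degenerate_targets("single-class labels: AUROC/AUPRC undefined"))
  }
  pred_pos <- scores >= threshold
  tp <- sum(pred_pos & y == 1)
  fp <- sum(pred_pos & y == 0)
  fn <- sum(!pred_pos & y == 1)
  list(
    AUROC = rank_auroc(y, scores),
    AUPRC = average_precision(y, scores),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = tp / (tp + fn)
  )
}
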