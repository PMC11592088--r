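#' Rank-based ROC-AUC
#'
#' Mann-Whitney formulation with ties averaged: the probability that a
#' random positive case scores above a random negative one (ties count
#' half).
#'
#' @param y_true labels.
#' @param score continuous scores (higher = more positive).
#' @param positive positive-class label.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
roc_auc <- function(y_true, score, positive) {
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix performance metrics
#'
#' Computes ROC-AUC, accuracy, sensitivity, specificity, PPV and NPV (as
#' percentages) with the stated positive class. Sensitivity is the recall of
#' the positive class; swap `positive` to obtain the opposite orientation.
#'
#' @param y_true true labels.
#' @param y_pred predicted hard labels.
#' @param y_score continuous scores for AUC (optional; AUC is `NA` when
#'   absent).
#' @param positive positive-class label (default `"malignant"`).
#' @return Named numeric vector (percent scale): `roc_auc`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`. Undefined ratios (empty
#'   denominator) are `NA`.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL,
                            positive = "malignant") {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  auc <- if (is.null(y_score)) NA_real_ else roc_auc(y_true, y_score, positive)
  100 * c(roc_auc = auc,
          accuracy = div(tp + tn, tp + tn + fp + fn),
          sensitivity = div(tp, tp + fn),
          specificity = div(tn, tn + fp),
          ppv = div(tp, tp + fp),
          npv = div(tn, tn + fn))
}

#' One-sided Wilcoxon signed-rank test against a chance level
#'
#' Tests whether metric samples exceed the null level (exact for small
#' samples without ties, normal approximation with tie/continuity correction
#' otherwise). All differences zero returns `p = 1`.
#'
#' @param samples numeric metric samples (percent scale), length >= 5
#'   recommended.
#' @param null_level chance level on the same scale: 50 for ROC-AUC,
#'   accuracy, sensitivity and specificity; the positive-class prevalence
#'   for PPV and the negative-class prevalence for NPV (28 and 72 here when
#'   malignant is positive; 72 and 28 under the benign-positive
#'   orientation).
#' @return One-sided p-value (alternative: greater).
#' @export
wilcoxon_vs_chance <- function(samples, null_level) {
  d <- samples - null_level
  d <- d[!is.na(d)]
  if (length(d) == 0 || all(d == 0)) return(1)
  res <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "greater"))
  unname(res$p.value)
}

# internal: the chance levels for the six metrics given class prevalences
null_levels <- function(prev_positive = 28, prev_negative = 72) {
  c(roc_auc = 50, accuracy = 50, sensitivity = 50, specificity = 50,
    ppv = prev_positive, npv = prev_negative)
}

#' Summarize member-level metric samples into a reporting row set
#'
#' Means with normal-approximation 95% CIs over the member samples, plus the
#' one-sided signed-rank p-value of each metric against its chance level.
#'
#' @param samples data.frame of member-level metrics (columns = the six
#'   metric names, percent scale).
#' @param nulls named chance levels from [null_levels()].
#' @param stage stage tag stored on the result.
#' @return data.frame: `stage`, `metric`, `value`, `ci_lo`, `ci_hi`, `p`.
#' @export
summarize_metric_samples <- function(samples, nulls = null_levels(),
                                     stage = "internal_mean") {
  metrics <- names(nulls)
  rows <- lapply(metrics, function(m) {
    x <- samples[[m]]
    x <- x[!is.na(x)]
    n <- length(x)
    mu <- mean(x)
    half <- if (n > 1) 1.96 * stats::sd(x) / sqrt(n) else 0
    data.frame(stage = stage, metric = m, value = mu,
               ci_lo = clamp(mu - half, 0, 100),
               ci_hi = clamp(mu + half, 0, 100),
               p = wilcoxon_vs_chance(x, nulls[[m]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# internal: Wilson score 95% CI for a proportion (as percentages)
wilson_ci <- function(k, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- 1.96
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  100 * c(ctr - half, ctr + half)
}

# internal: Hanley-McNeil standard error CI for an AUC (fraction scale in,
# percent out)
auc_ci <- function(auc, n_pos, n_neg) {
  if (is.na(auc)) return(c(NA_real_, NA_real_))
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
              (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  100 * clamp(c(auc - 1.96 * se, auc + 1.96 * se), 0, 1)
}

#' Metrics of one pooled prediction set with exact-count CIs
#'
#' Wilson score intervals for the proportion metrics and a Hanley-McNeil
#' interval for the AUC; used for majority-vote and external-test stages
#' where each case is predicted once.
#'
#' @param y_true,y_pred,y_score as in [compute_metrics()].
#' @param positive positive-class label.
#' @param stage stage tag.
#' @return data.frame: `stage`, `metric`, `value`, `ci_lo`, `ci_hi`, `p`
#'   (p is `NA`; no replicate samples exist at this stage).
#' @export
pooled_metric_set <- function(y_true, y_pred, y_score = NULL,
                              positive = "malignant", stage = "external") {
  m <- compute_metrics(y_true, y_pred, y_score, positive)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  cis <- list(
    roc_auc = auc_ci(m[["roc_auc"]] / 100, tp + fn, tn + fp),
    accuracy = wilson_ci(tp + tn, tp + tn + fp + fn),
    sensitivity = wilson_ci(tp, tp + fn),
    specificity = wilson_ci(tn, tn + fp),
    ppv = wilson_ci(tp, tp + fp),
    npv = wilson_ci(tn, tn + fn))
  do.call(rbind, lapply(names(cis), function(k) {
    data.frame(stage = stage, metric = k, value = m[[k]],
               ci_lo = cis[[k]][1], ci_hi = cis[[k]][2], p = NA_real_,
               stringsAsFactors = FALSE)
  }))
}
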