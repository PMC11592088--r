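#' Distribution-free 95% confidence interval for a median
#'
#' Binomial order-statistic bounds: the interval runs from the
#' `qbinom(0.025, n, 0.5)`-th to the `(qbinom(0.975, n, 0.5) + 1)`-th order
#' statistic (clamped to the sample range).
#'
#' @param x numeric sample.
#' @return Numeric `c(median, lo, hi)`.
#' @export
median_ci <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
  lo <- max(1L, stats::qbinom(0.025, n, 0.5))
  hi <- min(n, stats::qbinom(0.975, n, 0.5) + 1L)
  c(median = stats::median(x), lo = x[lo], hi = x[hi])
}

#' Univariate Mann-Whitney statistics for the selected features
#'
#' Per feature: class medians with distribution-free 95% CIs, the
#' Mann-Whitney U statistic (with respect to the malignant class), the
#' exact (or, under ties, normal-approximation) two-sided p-value, and
#' Bonferroni-Holm-adjusted p-values over the selected set, with
#' significance stars at 0.05 (`*`) and 0.005 (`**`). Rows are ordered by
#' adjusted then raw p-value.
#'
#' @param table feature data.frame (`case_id`, `label`, features).
#' @param features character vector of feature columns to test (default all).
#' @param class_a,class_b the two class labels (default
#'   benign / malignant).
#' @return data.frame with one row per feature: medians + CIs per class,
#'   `statistic_u`, `p_raw`, `p_holm`, `stars`.
#' @export
univariate_feature_stats <- function(table, features = NULL,
                                     class_a = "benign",
                                     class_b = "malignant") {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (is.null(features))
    features <- setdiff(names(table), c("case_id", "label"))
  if (length(features) == 0) {
    warning("empty selected-feature set; returning empty stats table")
    return(data.frame())
  }
  ga <- table$label == class_a
  gb <- table$label == class_b
  stopifnot(sum(ga) >= 2, sum(gb) >= 2)
  rows <- lapply(features, function(f) {
    xa <- table[[f]][ga]; xb <- table[[f]][gb]
    ca <- median_ci(xa); cb <- median_ci(xb)
    if (stats::sd(c(xa, xb)) == 0) {
      u <- length(xa) * length(xb) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(xb, xa, exact = NULL))
      u <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(feature = f,
               median_benign = ca[1], ci_lo_benign = ca[2],
               ci_hi_benign = ca[3],
               median_malignant = cb[1], ci_lo_malignant = cb[2],
               ci_hi_malignant = cb[3],
               statistic_u = u, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out$stars <- ifelse(out$p_holm < 0.005, "**",
                      ifelse(out$p_holm < 0.05, "*", ""))
  out <- out[order(out$p_holm, out$p_raw), ]
  rownames(out) <- NULL
  out
}
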