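#' Intensity-based statistical features of ROI values
#'
#' First-order statistics of the (continuous, pre-discretization) ROI
#' intensities. Variance, skewness and kurtosis use population (biased)
#' moments; kurtosis is excess kurtosis; zero-variance ROIs return 0 for
#' skewness and kurtosis. Percentiles use linear interpolation between order
#' statistics (R quantile type 7), the convention used consistently across
#' this package. The quartile coefficient of dispersion is
#' `(P75 - P25) / (P75 + P25)`; when `P75 + P25 = 0` it is returned as 0
#' with a warning.
#'
#' @param x numeric vector of ROI intensities (at least one value).
#' @return Named numeric vector of 17 features.
#' @export
intensity_statistics <- function(x) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  mo <- moments_pop(x)
  denom <- q[4] + q[2]
  qcd <- if (denom == 0) {
    warning("quartile coefficient undefined (P75 + P25 = 0); returning 0")
    0
  } else (q[4] - q[2]) / denom
  c(mean = mo$mean, variance = mo$var, skewness = mo$skew,
    kurtosis = mo$kurt, median = q[3], minimum = min(x), maximum = max(x),
    p10 = q[1], p25 = q[2], p75 = q[4], p90 = q[5],
    interquartile_range = q[4] - q[2], quartile_coefficient = qcd,
    range = max(x) - min(x), mean_absolute_deviation = mean(abs(x - mo$mean)),
    energy = sum(x^2), root_mean_square = sqrt(mean(x^2)))
}

#' Intensity-histogram features of a discretized ROI
#'
#' First-order statistics of the grey levels `1..n_bins` after
#' fixed-bin-number discretization. Entropy is in bits (log base 2);
#' uniformity is the sum of squared level probabilities; the mode is the
#' most frequent level (lowest level on ties).
#'
#' @param d a `disc_roi` from [discretize_fbn()].
#' @return Named numeric vector of 10 features.
#' @export
intensity_histogram_features <- function(d) {
  stopifnot(inherits(d, "disc_roi"))
  lv <- d$levels[!is.na(d$levels)]
  n <- length(lv)
  counts <- tabulate(lv, nbins = d$n_bins)
  p <- counts / n
  pos <- p[p > 0]
  mo <- moments_pop(lv)
  c(mean = mo$mean, variance = mo$var, skewness = mo$skew,
    kurtosis = mo$kurt,
    median = stats::quantile(lv, 0.5, names = FALSE, type = 7),
    mode = which.max(counts),
    entropy = -sum(pos * log2(pos)), uniformity = sum(pos^2),
    min_grey_level = min(lv), max_grey_level = max(lv))
}
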