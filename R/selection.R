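#' Feature-screening configuration
#'
#' Two univariate screens applied in order: (1) drop features whose sample
#' variance (unbiased, raw feature scale) falls below `variance_threshold`;
#' (2) estimate each surviving feature's mutual information with the binary
#' class label (plug-in estimate in nats after equal-frequency discretization
#' into `mi_bins` bins) and keep features whose MI is at least
#' `mi_threshold`. Keeping (rather than removing) high-MI features makes the
#' surviving set the most informative one; set `mi_keep_high = FALSE` for
#' the opposite (literal low-MI) reading.
#'
#' @param variance_threshold minimum sample variance (default 0.1).
#' @param mi_threshold minimum MI with the label in nats (default 0.19).
#' @param mi_bins equal-frequency bins for MI estimation (default 10).
#' @param mi_keep_high keep features with MI >= threshold (default TRUE).
#' @return A `selection_config` list.
#' @export
selection_config <- function(variance_threshold = 0.1, mi_threshold = 0.19,
                             mi_bins = 10L, mi_keep_high = TRUE) {
  stopifnot(variance_threshold >= 0, mi_threshold >= 0, mi_bins >= 2)
  structure(list(variance_threshold = variance_threshold,
                 mi_threshold = mi_threshold, mi_bins = as.integer(mi_bins),
                 mi_keep_high = isTRUE(mi_keep_high)),
            class = "selection_config")
}

#' Variance screen
#'
#' @param X numeric feature matrix (cases x features).
#' @param cfg a [selection_config].
#' @return data.frame fragment: `feature`, `variance`, `keep_variance`.
#' @export
variance_filter <- function(X, cfg = selection_config()) {
  stopifnot(is.matrix(X), nrow(X) >= 2)
  v <- apply(X, 2, stats::var)
  data.frame(feature = colnames(X), variance = as.numeric(v),
             keep_variance = as.numeric(v) >= cfg$variance_threshold,
             stringsAsFactors = FALSE)
}

# internal: equal-frequency discretization into at most `bins` bins
equal_freq_bins <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

# internal: plug-in mutual information (nats) of a discrete pair
mi_nats <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  ind <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / ind[nz]))
}

#' Mutual-information screen against the class label
#'
#' @param X numeric feature matrix.
#' @param y class labels (two classes).
#' @param cfg a [selection_config].
#' @return data.frame fragment: `feature`, `mi`, `keep_mi`.
#' @export
mutual_information_filter <- function(X, y, cfg = selection_config()) {
  stopifnot(is.matrix(X))
  if (length(unique(y)) < 2) {
    warning("single-class labels: MI screen is a no-op")
    return(data.frame(feature = colnames(X), mi = NA_real_,
                      keep_mi = TRUE, stringsAsFactors = FALSE))
  }
  bins <- cfg$mi_bins
  if (nrow(X) < bins) {
    warning("fewer cases than MI bins; reducing bins to ", nrow(X))
    bins <- nrow(X)
  }
  mi <- apply(X, 2, function(x) mi_nats(equal_freq_bins(x, bins), y))
  keep <- if (cfg$mi_keep_high) mi >= cfg$mi_threshold
          else mi < cfg$mi_threshold
  data.frame(feature = colnames(X), mi = as.numeric(mi), keep_mi = keep,
             stringsAsFactors = FALSE)
}

#' Run the two-step feature screen
#'
#' Variance screen then MI screen; surviving column order is preserved.
#' Selection is deterministic given the table. Errors if no feature
#' survives.
#'
#' @param table feature data.frame (`case_id`, `label`, features) or a
#'   numeric matrix (then `y` must be given).
#' @param y labels (taken from `table$label` when `table` is a data.frame).
#' @param cfg a [selection_config].
#' @return list: `table` (surviving columns, same format as input) and
#'   `report` (per-feature variance, MI, kept flag, drop reason).
#' @export
run_selection <- function(table, y = NULL, cfg = selection_config()) {
  if (is.data.frame(table)) {
    fm <- feature_matrix(table)
    X <- fm$X
    if (is.null(y)) y <- fm$y
  } else {
    X <- table
    stopifnot(!is.null(y))
  }
  vf <- variance_filter(X, cfg)
  keep1 <- vf$feature[vf$keep_variance]
  mif <- if (length(keep1) > 0) {
    mutual_information_filter(X[, keep1, drop = FALSE], y, cfg)
  } else {
    data.frame(feature = character(0), mi = numeric(0),
               keep_mi = logical(0), stringsAsFactors = FALSE)
  }
  report <- merge(vf, mif, by = "feature", all.x = TRUE, sort = FALSE)
  report <- report[match(vf$feature, report$feature), ]
  report$keep_mi[is.na(report$keep_mi)] <- FALSE
  report$kept <- report$keep_variance & report$keep_mi
  report$drop_reason <- ifelse(report$kept, "",
                               ifelse(!report$keep_variance, "low_variance",
                                      "mutual_information"))
  surviving <- report$feature[report$kept]
  if (length(surviving) == 0)
    stop("no features survive selection; consider lowering the thresholds")
  out <- if (is.data.frame(table)) {
    table[, c("case_id", "label", surviving), drop = FALSE]
  } else {
    X[, surviving, drop = FALSE]
  }
  rownames(report) <- NULL
  list(table = out, report = report, selected = surviving)
}
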