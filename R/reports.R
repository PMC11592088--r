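#' ROC curve coordinates for a prediction set
#'
#' @param y_true labels.
#' @param score continuous scores.
#' @param positive positive-class label.
#' @return data.frame of `threshold`, `fpr`, `tpr` (thresholds swept over
#'   the unique scores plus sentinels).
#' @export
roc_coordinates <- function(y_true, score, positive = "malignant") {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  do.call(rbind, lapply(thr, function(t) {
    pred <- score >= t
    data.frame(threshold = t,
               fpr = if (n0 > 0) sum(pred & !pos) / n0 else NA_real_,
               tpr = if (n1 > 0) sum(pred & pos) / n1 else NA_real_)
  }))
}

#' Export the full evaluation report set
#'
#' Writes, under `dir`: the stage-by-metric table of every model
#' (`metrics.csv` + `metrics.json`), the external-test metrics and per-case
#' predictions, the feature-selection report, the univariate statistics
#' table, per-feature per-class value dumps sufficient to draw violin/box
#' plots, and per-rotation internal-test ROC coordinates of every model.
#'
#' @param dir output directory (created if needed).
#' @param cv_results named list of `cv_result` objects.
#' @param external result of [external_test()] (or `NULL`).
#' @param selection result of [run_selection()] (or `NULL`).
#' @param univariate result of [univariate_feature_stats()] (or `NULL`).
#' @param table selected feature table for the value dumps (or `NULL`).
#' @return `dir`, invisibly.
#' @export
export_reports <- function(dir, cv_results, external = NULL,
                           selection = NULL, univariate = NULL,
                           table = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- do.call(rbind, lapply(names(cv_results), function(m) {
    cbind(model = m, cv_results[[m]]$summary)
  }))
  utils::write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       dataframe = "rows", digits = NA)
  for (m in names(cv_results)) {
    res <- cv_results[[m]]
    roc <- do.call(rbind, lapply(seq_len(res$plan$n_folds), function(r) {
      sub <- res$pooled_test[res$pooled_test$rotation == r, ]
      cbind(rotation = r,
            roc_coordinates(sub$true, sub$score,
                            res$spec$positive_class))
    }))
    utils::write.csv(roc, file.path(dir, paste0("roc_", m, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(external)) {
    utils::write.csv(external$metrics, file.path(dir, "external_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(external$predictions,
                     file.path(dir, "external_predictions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(selection)) {
    utils::write.csv(selection$report, file.path(dir, "selection_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(selection$selected,
                         file.path(dir, "selected_features.json"), digits = NA)
  }
  if (!is.null(univariate)) {
    utils::write.csv(univariate, file.path(dir, "univariate_stats.csv"),
                     row.names = FALSE)
  }
  if (!is.null(table)) {
    keep <- intersect(names(table),
                      c("case_id", "label",
                        if (!is.null(univariate)) univariate$feature
                        else names(table)))
    long <- stats::reshape(
      table[, keep, drop = FALSE],
      varying = setdiff(keep, c("case_id", "label")),
      v.names = "value", timevar = "feature",
      times = setdiff(keep, c("case_id", "label")),
      direction = "long")
    rownames(long) <- NULL
    long$id <- NULL
    utils::write.csv(long, file.path(dir, "feature_values_long.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
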