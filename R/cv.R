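#' Build a stratified nested 4-fold cross-validation plan
#'
#' Cases are shuffled within class (seeded) and dealt round-robin into
#' `n_folds` disjoint folds, so per-fold class counts stay within one case
#' of the global ratio. The plan defines one rotation per fold: the fold is
#' the internal-test fold, the next fold (cyclically) is the validation
#' fold, and the remaining folds form the training set; each fold is the
#' internal-test fold in exactly one rotation.
#'
#' @param labels class label vector (both classes in every fold required).
#' @param seed integer seed.
#' @param n_folds number of folds (default 4).
#' @return A `cv_plan`: `fold` (integer per case), `rotations` (list of
#'   `train`/`validation`/`test` index vectors), `seed`.
#' @export
make_cv_plan <- function(labels, seed = 1L, n_folds = 4L) {
  n <- length(labels)
  stopifnot(n >= 2 * n_folds)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "cv_plan"))
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < n_folds)
      stop("class '", cl, "' too small to stratify into ", n_folds, " folds")
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  rotations <- lapply(seq_len(n_folds), function(r) {
    test <- which(fold == r)
    val <- which(fold == (r %% n_folds) + 1L)
    train <- which(!fold %in% c(r, (r %% n_folds) + 1L))
    list(train = train, validation = val, test = test)
  })
  structure(list(fold = fold, rotations = rotations, n_folds = n_folds,
                 seed = as.integer(seed)), class = "cv_plan")
}

# internal: member-level metric samples for one prediction stage
member_metric_rows <- function(mp, y_true, positive, rotation, stage) {
  do.call(rbind, lapply(seq_len(ncol(mp$prob)), function(m) {
    v <- compute_metrics(y_true, mp$label[, m], mp$prob[, m], positive)
    data.frame(rotation = rotation, member = m, stage = stage, t(v),
               stringsAsFactors = FALSE)
  }))
}

#' Run one ensemble architecture through the nested cross-validation
#'
#' Per rotation: ADASYN is applied to the two training folds only (the
#' validation and internal-test folds never influence oversampling,
#' standardization or PCA), the ensemble is fitted on the balanced training
#' data, and member-level metrics are computed on the training, validation
#' and internal-test folds. Reporting stages follow the study layout:
#' `training`, `validation` and `internal_mean` average the member-level
#' metrics across all rotations (16 members x 4 rotations = 64 samples per
#' metric), and `internal_majority` scores the pooled majority-vote
#' predictions, each case being predicted by the single rotation whose test
#' fold contains it.
#'
#' @param X selected feature matrix (cases x features).
#' @param y class labels.
#' @param spec an [ensemble_spec].
#' @param plan a [make_cv_plan()] result.
#' @param adasyn an [adasyn_config].
#' @param seed integer seed for ensemble fitting.
#' @return A `cv_result`: fitted `ensembles` (one per rotation),
#'   `member_metrics` (long data.frame of per-member samples),
#'   `summary` (stage x metric reporting table), `pooled_test`
#'   (per-case majority-vote internal-test predictions), `plan`, `spec`.
#' @export
run_nested_cv <- function(X, y, spec = ensemble_spec(), plan,
                          adasyn = adasyn_config(), seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y),
            inherits(plan, "cv_plan"))
  pos <- spec$positive_class
  prev_pos <- round(100 * mean(y == pos))
  nulls <- null_levels(prev_positive = prev_pos,
                       prev_negative = 100 - prev_pos)
  ensembles <- vector("list", plan$n_folds)
  mm <- list()
  pooled <- list()
  for (r in seq_len(plan$n_folds)) {
    rot <- plan$rotations[[r]]
    acfg <- adasyn_config(beta = adasyn$beta, k_neighbors = adasyn$k_neighbors,
                          seed = derive_seed(seed, paste0("adasyn_", r)))
    bal <- adasyn_oversample(X[rot$train, , drop = FALSE], y[rot$train],
                             acfg, minority_class = pos)
    ens <- fit_ensemble(bal$X, bal$y, spec,
                        seed = derive_seed(seed, paste0("ensemble_", r)))
    ensembles[[r]] <- ens
    for (stage in c("training", "validation", "test")) {
      idx <- switch(stage, training = rot$train, validation = rot$validation,
                    test = rot$test)
      mp <- member_predictions(ens, X[idx, , drop = FALSE])
      mm[[paste(r, stage)]] <- member_metric_rows(mp, y[idx], pos, r, stage)
    }
    pr <- predict(ens, X[rot$test, , drop = FALSE])
    pr$true <- y[rot$test]
    pr$rotation <- r
    pooled[[r]] <- pr
  }
  member_metrics <- do.call(rbind, mm)
  rownames(member_metrics) <- NULL
  pooled <- do.call(rbind, pooled)
  summary <- rbind(
    summarize_metric_samples(member_metrics[member_metrics$stage == "training",
                                            ], nulls, "training"),
    summarize_metric_samples(
      member_metrics[member_metrics$stage == "validation", ], nulls,
      "validation"),
    summarize_metric_samples(member_metrics[member_metrics$stage == "test", ],
                             nulls, "internal_mean"),
    pooled_metric_set(pooled$true, pooled$label, pooled$score, pos,
                      "internal_majority"))
  structure(list(ensembles = ensembles, member_metrics = member_metrics,
                 summary = summary, pooled_test = pooled, plan = plan,
                 spec = spec),
            class = "cv_result")
}

#' Select the best model by internal-test mean ROC-AUC
#'
#' Argmax of the `internal_mean` ROC-AUC; ties broken by the
#' `internal_majority` ROC-AUC, then by model order.
#'
#' @param cv_results named list of `cv_result` objects (one per model kind).
#' @return The name of the winning model.
#' @export
select_best_model <- function(cv_results) {
  stopifnot(length(cv_results) >= 1)
  score <- function(res, stage) {
    s <- res$summary
    s$value[s$stage == stage & s$metric == "roc_auc"]
  }
  mean_auc <- vapply(cv_results, score, numeric(1), stage = "internal_mean")
  maj_auc <- vapply(cv_results, score, numeric(1), stage = "internal_majority")
  ord <- order(-mean_auc, -maj_auc, seq_along(cv_results))
  names(cv_results)[ord[1]]
}

#' Externally test the selected model
#'
#' Pools the member votes of all rotation ensembles (e.g. 4 x 16 = 64
#' members) on every external case: the hard label is the majority of all
#' member votes and the score is the mean member positive-class
#' probability.
#'
#' @param cv_result a `cv_result` (the best model's).
#' @param X_ext external feature matrix with the training schema.
#' @param y_ext external labels.
#' @param positive positive-class label (defaults to the spec's).
#' @return list: `metrics` (stage-tagged data.frame, both orientations),
#'   `predictions` (per-case data.frame).
#' @export
external_test <- function(cv_result, X_ext, y_ext, positive = NULL) {
  stopifnot(inherits(cv_result, "cv_result"))
  if (is.null(positive)) positive <- cv_result$spec$positive_class
  probs <- do.call(cbind, lapply(cv_result$ensembles, function(ens) {
    member_predictions(ens, X_ext)$prob
  }))
  vf <- rowMeans(probs >= 0.5)
  score <- rowMeans(probs)
  classes <- cv_result$ensembles[[1]]$classes
  neg <- setdiff(classes, positive)[1]
  tie_pos <- cv_result$spec$tie_positive
  lab <- ifelse(vf > 0.5 | (vf == 0.5 & tie_pos), positive, neg)
  preds <- data.frame(case_id = if (!is.null(rownames(X_ext)))
                        rownames(X_ext) else as.character(seq_along(y_ext)),
                      true = y_ext, label = lab, vote_fraction = vf,
                      score = score, stringsAsFactors = FALSE)
  met_pos <- pooled_metric_set(y_ext, lab, score, positive, "external")
  met_neg <- pooled_metric_set(y_ext, lab, 1 - score, neg,
                               "external_benign_positive")
  list(metrics = rbind(met_pos, met_neg), predictions = preds)
}
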