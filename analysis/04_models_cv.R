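#!/usr/bin/env Rscript
# Train and evaluate the three majority-vote ensemble architectures (random
# forest with Gini; PCA+FDR SVM; PCA+FDR kNN; 16 members each) under nested
# 4-fold cross-validation with ADASYN applied to the training folds only.
source("analysis/00_config.R")

tab <- utils::read.csv(file.path(STUDY_DIR, "features_selected.csv"),
                       check.names = FALSE)
fm <- feature_matrix(tab)
plan <- make_cv_plan(fm$y, seed = derive_seed(SEED, "folds"))

models <- list(rf = ensemble_spec("random_forest"),
               svm = ensemble_spec("svm_pca_fdr"),
               knn = ensemble_spec("knn_pca_fdr"))

cv_results <- lapply(names(models), function(m) {
  message("nested CV: model ", m)
  run_nested_cv(fm$X, fm$y, models[[m]], plan,
                adasyn_config(seed = derive_seed(SEED, paste0("ad_", m))),
                seed = derive_seed(SEED, paste0("model_", m)))
})
names(cv_results) <- names(models)

for (m in names(cv_results)) {
  s <- cv_results[[m]]$summary
  auc <- function(stage) round(s$value[s$stage == stage &
                                         s$metric == "roc_auc"], 1)
  message(sprintf(
    "  %s ROC-AUC: training %.1f, validation %.1f, internal mean %.1f, majority vote %.1f",
    m, auc("training"), auc("validation"), auc("internal_mean"),
    auc("internal_majority")))
}

best <- select_best_model(cv_results)
message("best model by internal-test mean ROC-AUC: ", best)

export_reports(STUDY_DIR, cv_results)
saveRDS(list(cv_results = cv_results, best = best, plan = plan),
        file.path(STUDY_DIR, "cv_results.rds"))  # working artefact
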