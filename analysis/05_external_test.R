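#!/usr/bin/env Rscript
# Externally test the best model: pooled majority vote of all 64 members
# (4 rotation ensembles x 16) on the 21 external cases, reported in both
# class orientations with score CIs.
source("analysis/00_config.R")

state <- readRDS(file.path(STUDY_DIR, "cv_results.rds"))
tab <- utils::read.csv(file.path(STUDY_DIR, "features_selected.csv"),
                       check.names = FALSE)
fe <- utils::read.csv(file.path(STUDY_DIR, "features_external.csv"),
                      check.names = FALSE)

efm <- feature_matrix(fe[, names(tab), drop = FALSE])
et <- external_test(state$cv_results[[state$best]], efm$X, efm$y)

utils::write.csv(et$metrics, file.path(STUDY_DIR, "external_metrics.csv"),
                 row.names = FALSE)
utils::write.csv(et$predictions,
                 file.path(STUDY_DIR, "external_predictions.csv"),
                 row.names = FALSE)

em <- et$metrics[et$metrics$stage == "external", ]
for (i in seq_len(nrow(em))) {
  message(sprintf("  external %s: %.1f%% [%.1f, %.1f]", em$metric[i],
                  em$value[i], em$ci_lo[i], em$ci_hi[i]))
}
tp <- sum(et$predictions$true == "malignant" &
            et$predictions$label == "malignant")
message("identified ", tp, " of ", sum(et$predictions$true == "malignant"),
        " malignant nodules")
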