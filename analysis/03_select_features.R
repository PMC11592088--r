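#!/usr/bin/env Rscript
# Two-step univariate screen on the training features: drop sample variance
# < 0.1, then keep mutual information with the class label >= 0.19 nats
# (10 equal-frequency bins).
source("analysis/00_config.R")

ft <- utils::read.csv(file.path(STUDY_DIR, "features_train.csv"),
                      check.names = FALSE)
sel <- run_selection(ft)

utils::write.csv(sel$report, file.path(STUDY_DIR, "selection_report.csv"),
                 row.names = FALSE)
utils::write.csv(sel$table, file.path(STUDY_DIR, "features_selected.csv"),
                 row.names = FALSE)

n_var <- sum(!sel$report$keep_variance)
n_mi <- sum(sel$report$keep_variance & !sel$report$keep_mi)
message(nrow(sel$report), " features in; ", n_var,
        " dropped by the variance screen, ", n_mi,
        " by the MI screen; ", length(sel$selected), " survive")
fams <- table(sub("^[a-z]+__([a-z]+)__.*$", "\\1", sel$selected))
message("surviving families: ",
        paste(names(fams), fams, sep = "=", collapse = ", "))
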