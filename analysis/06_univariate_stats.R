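#!/usr/bin/env Rscript
# Univariate Mann-Whitney statistics for the selected radiomic predictors:
# class medians with distribution-free 95% CIs, exact U-test p-values,
# Bonferroni-Holm adjustment, and the long-format per-case value dump used
# for violin/box plots.
source("analysis/00_config.R")

tab <- utils::read.csv(file.path(STUDY_DIR, "features_selected.csv"),
                       check.names = FALSE)
uni <- univariate_feature_stats(tab)

utils::write.csv(uni, file.path(STUDY_DIR, "univariate_stats.csv"),
                 row.names = FALSE)
long <- stats::reshape(tab, varying = setdiff(names(tab),
                                              c("case_id", "label")),
                       v.names = "value", timevar = "feature",
                       times = setdiff(names(tab), c("case_id", "label")),
                       direction = "long")
long$id <- NULL
utils::write.csv(long, file.path(STUDY_DIR, "feature_values_long.csv"),
                 row.names = FALSE)

message(sum(uni$p_holm < 0.005), " of ", nrow(uni),
        " selected features significant at the 0.005 level after Holm")
message("top discriminators by adjusted p:")
top <- utils::head(uni[, c("feature", "median_benign", "median_malignant",
                           "p_holm")], 10)
print(top, row.names = FALSE)
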