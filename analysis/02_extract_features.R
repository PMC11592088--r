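#!/usr/bin/env Rscript
# Extract the radiomic feature bank for both cohorts: 5 filters (identity,
# gradient, LoG, square, square root) x 7 families (intensity statistics,
# intensity histogram, GLCM, GLRLM, GLSZM, NGTDM, NGLDM) per case, after
# isotropic resampling and fixed-bin-number (64) discretization.
source("analysis/00_config.R")

train <- read_cohort(file.path(STUDY_DIR, "cohort_train"))
external <- read_cohort(file.path(STUDY_DIR, "cohort_external"))

message("extracting features for ", length(train), " training cases")
ft <- extract_cohort(train, verbose = TRUE)
message("extracting features for ", length(external), " external cases")
fe <- extract_cohort(external)

utils::write.csv(ft, file.path(STUDY_DIR, "features_train.csv"),
                 row.names = FALSE)
utils::write.csv(fe, file.path(STUDY_DIR, "features_external.csv"),
                 row.names = FALSE)
message("feature bank: ", ncol(ft) - 2, " features per case")
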