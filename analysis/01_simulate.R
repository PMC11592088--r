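#!/usr/bin/env Rscript
# Simulate the study cohorts: 142 training/internal cases (102 benign, 40
# malignant) and 21 external cases (15 benign, 6 malignant), written as PNG
# images, 0/255 PNG masks, a label CSV and a JSON manifest per cohort.
source("analysis/00_config.R")

cfg_tr <- scaled_train_config()
cfg_ex <- scaled_external_config()

message("simulating ", cfg_tr$n_benign + cfg_tr$n_malignant,
        " training cases and ", cfg_ex$n_benign + cfg_ex$n_malignant,
        " external cases")
train <- generate_cohort(cfg_tr)
external <- generate_cohort(cfg_ex)

write_cohort(train, file.path(STUDY_DIR, "cohort_train"), cfg_tr)
write_cohort(external, file.path(STUDY_DIR, "cohort_external"), cfg_ex)

lab <- cohort_labels(train)
message("training cohort: ", sum(lab$label == "malignant"), " malignant (",
        round(100 * mean(lab$label == "malignant"), 1), "%), ",
        sum(lab$label == "benign"), " benign")
message("wrote cohorts under ", STUDY_DIR)
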