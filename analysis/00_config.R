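# Shared configuration for the analysis scripts: the desk-scale study
# conditions (96 x 96 images, full 142-case training and 21-case external
# cohorts) and a single global seed that every stage derives from.
library(usradiomics)

SEED <- 20240901L
STUDY_DIR <- "results/study"

scaled_train_config <- function() {
  cohort_config(image_height = 96L, image_width = 96L,
                roi_axes_range = c(12, 24), focus_radius_range = c(2, 3),
                macro_correlation_px = 3,
                seed = derive_seed(SEED, "cohort"))
}

scaled_external_config <- function() {
  external_cohort_config(image_height = 96L, image_width = 96L,
                         roi_axes_range = c(12, 24),
                         focus_radius_range = c(2, 3),
                         macro_correlation_px = 3,
                         seed = derive_seed(SEED, "external"))
}

dir.create(STUDY_DIR, recursive = TRUE, showWarnings = FALSE)
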