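#' Full-study run configuration
#'
#' One structured config for the whole pipeline. A single global seed fans
#' out deterministically to every stage through [derive_seed()]; re-running
#' with the same config reproduces every output table byte-for-byte.
#'
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @param cohort training/internal [cohort_config] (seed is overridden by
#'   the global seed's `cohort` substream).
#' @param external_cohort external [cohort_config].
#' @param prep a [prep_config].
#' @param filters filter bank from [default_filter_bank()].
#' @param tex a [texture_config].
#' @param selection a [selection_config].
#' @param adasyn an [adasyn_config].
#' @param models named list of [ensemble_spec] (default the three study
#'   architectures: `rf`, `svm`, `knn`).
#' @param write_images also write the cohorts to disk as PNG + CSV
#'   (default FALSE; feature tables and reports are always written).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = "run",
                       cohort = cohort_config(),
                       external_cohort = external_cohort_config(),
                       prep = prep_config(),
                       filters = default_filter_bank(),
                       tex = texture_config(),
                       selection = selection_config(),
                       adasyn = adasyn_config(),
                       models = list(
                         rf = ensemble_spec("random_forest"),
                         svm = ensemble_spec("svm_pca_fdr"),
                         knn = ensemble_spec("knn_pca_fdr")),
                       write_images = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, cohort = cohort,
                 external_cohort = external_cohort, prep = prep,
                 filters = filters, tex = tex, selection = selection,
                 adasyn = adasyn, models = models,
                 write_images = isTRUE(write_images)),
            class = "run_config")
}

#' Run the complete study pipeline
#'
#' simulate -> extract -> select -> train/evaluate the three ensemble
#' architectures under nested 4-fold cross-validation -> pick the best model
#' by internal-test mean ROC-AUC -> external test -> univariate feature
#' statistics -> report files. All stage outputs land under
#' `config$out_dir`; the JSON run manifest records the config, stage seeds
#' and MD5 hashes of every written table.
#'
#' @param config a [run_config].
#' @param verbose log stage progress (default TRUE).
#' @return A list with the in-memory results of every stage: `cohort`,
#'   `external_cohort`, `features`, `external_features`, `selection`,
#'   `cv_results`, `best_model`, `external`, `univariate`, `out_dir`.
#' @export
run_all <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("[1/7] simulating cohorts")
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- derive_seed(config$seed, "cohort")
  ext_cfg <- config$external_cohort
  ext_cfg$seed <- derive_seed(config$seed, "external")
  cases <- generate_cohort(cohort_cfg)
  ext_cases <- generate_cohort(ext_cfg)
  if (config$write_images) {
    write_cohort(cases, file.path(config$out_dir, "cohort"), cohort_cfg)
    write_cohort(ext_cases, file.path(config$out_dir, "external_cohort"),
                 ext_cfg)
  }

  say("[2/7] extracting radiomic features")
  feats <- extract_cohort(cases, config$prep, config$filters, config$tex,
                          verbose = verbose)
  ext_feats <- extract_cohort(ext_cases, config$prep, config$filters,
                              config$tex)
  utils::write.csv(feats, file.path(config$out_dir, "features_train.csv"),
                   row.names = FALSE)
  utils::write.csv(ext_feats,
                   file.path(config$out_dir, "features_external.csv"),
                   row.names = FALSE)

  say("[3/7] screening features")
  sel <- run_selection(feats, cfg = config$selection)
  say("      ", length(sel$selected), " features survive")

  say("[4/7] nested cross-validation of ", length(config$models), " models")
  fm <- feature_matrix(sel$table)
  plan <- make_cv_plan(fm$y, seed = derive_seed(config$seed, "folds"))
  cv_results <- lapply(names(config$models), function(m) {
    say("      model ", m)
    run_nested_cv(fm$X, fm$y, config$models[[m]], plan, config$adasyn,
                  seed = derive_seed(config$seed, paste0("model_", m)))
  })
  names(cv_results) <- names(config$models)

  say("[5/7] selecting the best model by internal-test mean ROC-AUC")
  best <- select_best_model(cv_results)
  say("      best model: ", best)

  say("[6/7] external testing")
  ext_fm <- feature_matrix(ext_feats[, names(sel$table), drop = FALSE])
  ext_res <- external_test(cv_results[[best]], ext_fm$X, ext_fm$y)

  say("[7/7] univariate statistics and reports")
  uni <- univariate_feature_stats(sel$table)
  export_reports(config$out_dir, cv_results, external = ext_res,
                 selection = sel, univariate = uni, table = sel$table)

  tables <- list.files(config$out_dir, pattern = "\\.(csv|json)$",
                       full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    stage_seeds = list(cohort = cohort_cfg$seed, external = ext_cfg$seed,
                       folds = derive_seed(config$seed, "folds")),
    n_train = length(cases), n_external = length(ext_cases),
    n_features = length(sel$report$feature),
    n_selected = length(sel$selected),
    best_model = best,
    hashes = as.list(tools::md5sum(tables)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  list(cohort = cases, external_cohort = ext_cases, features = feats,
       external_features = ext_feats, selection = sel,
       cv_results = cv_results, best_model = best, external = ext_res,
       univariate = uni, out_dir = config$out_dir)
}

#' A reduced-scale run configuration for repeated simulation studies
#'
#' Same cohort sizes and effect parameters as the default study conditions,
#' but 96 x 96 images with proportionally scaled ROI axes and focus radii,
#' so repeated end-to-end runs stay desk-cheap. Used by the package's
#' repeated-seed recovery and permutation analyses.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param ... further overrides passed to [run_config()].
#' @export
scaled_run_config <- function(seed = 1L, out_dir = "run_scaled", ...) {
  run_config(
    seed = seed, out_dir = out_dir,
    cohort = cohort_config(image_height = 96L, image_width = 96L,
                           roi_axes_range = c(12, 24),
                           focus_radius_range = c(2, 3),
                           macro_correlation_px = 3),
    external_cohort = external_cohort_config(
      image_height = 96L, image_width = 96L,
      roi_axes_range = c(12, 24), focus_radius_range = c(2, 3),
      macro_correlation_px = 3),
    ...)
}
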