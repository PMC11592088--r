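#' Extract the full radiomic feature vector for one case
#'
#' For each filter in the bank: apply the filter, resample the filtered
#' image/mask pair to isotropic spacing under the purpose-specific pixel
#' caps, then (a) compute intensity statistics on the continuous ROI values
#' of the "other"-purpose resampled image and (b) discretize the
#' "texture"-purpose resampled ROI with the fixed-bin-number rule and run
#' the histogram and all five texture-matrix families. Feature names follow
#' `<filter>__<family>__<feature>` (e.g.
#' `gradient__ngldm__dependence_count_energy`,
#' `square__ngtdm__complexity`).
#'
#' @param image a [gray_image].
#' @param mask a [roi_mask].
#' @param prep a [prep_config].
#' @param filters named list of [filter_spec] (default the five-filter bank).
#' @param tex a [texture_config].
#' @return Named numeric vector of features (identical name set for every
#'   case processed with the same configuration).
#' @export
extract_all <- function(image, mask, prep = prep_config(),
                        filters = default_filter_bank(),
                        tex = texture_config()) {
  check_pair(image, mask)
  out <- list()
  for (fname in names(filters)) {
    fimg <- apply_filter(image, filters[[fname]])
    res_t <- resample_isotropic(fimg, mask, prep, purpose = "texture")
    res_o <- resample_isotropic(fimg, mask, prep, purpose = "other")
    roi_vals <- res_o$image$values[res_o$mask$values]
    d <- discretize_fbn(res_t$image, res_t$mask, prep)
    fam <- tryCatch(
      list(stat  = intensity_statistics(roi_vals),
           hist  = intensity_histogram_features(d),
           glcm  = glcm_features(d, tex),
           glrlm = glrlm_features(d, tex),
           glszm = glszm_features(d),
           ngtdm = ngtdm_features(d, tex),
           ngldm = ngldm_features(d, tex)),
      error = function(e) stop("feature extraction failed for filter '",
                               fname, "': ", conditionMessage(e)))
    for (famname in names(fam)) {
      v <- fam[[famname]]
      names(v) <- paste(fname, famname, names(v), sep = "__")
      out[[paste(fname, famname, sep = "__")]] <- v
    }
  }
  unlist(unname(out))
}

#' Extract the feature table of a whole cohort
#'
#' @param cases list of `synthetic_case` (or any list with `case_id`,
#'   `label`, `image`, `mask`).
#' @param prep,filters,tex configurations passed to [extract_all()].
#' @param verbose print progress every 25 cases.
#' @return A data.frame: `case_id`, `label`, then one column per feature.
#' @export
extract_cohort <- function(cases, prep = prep_config(),
                           filters = default_filter_bank(),
                           tex = texture_config(), verbose = FALSE) {
  stopifnot(length(cases) >= 1)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    if (verbose && i %% 25L == 0L)
      message("  extracted ", i, "/", length(cases), " cases")
    tryCatch(extract_all(cs$image, cs$mask, prep, filters, tex),
             error = function(e) stop("case ", cs$case_id, ": ",
                                      conditionMessage(e)))
  })
  nm <- names(rows[[1]])
  for (r in rows) {
    if (!identical(names(r), nm)) stop("inconsistent feature schema in cohort")
  }
  mat <- do.call(rbind, rows)
  df <- data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
                   label = vapply(cases, `[[`, "", "label"),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Split a feature table into its numeric matrix and labels
#'
#' @param table data.frame from [extract_cohort()] (columns `case_id`,
#'   `label`, features).
#' @return list with `X` (numeric matrix, rownames = case ids) and `y`
#'   (character label vector).
#' @export
feature_matrix <- function(table) {
  stopifnot(all(c("case_id", "label") %in% names(table)))
  X <- as.matrix(table[, setdiff(names(table), c("case_id", "label")),
                       drop = FALSE])
  rownames(X) <- table$case_id
  list(X = X, y = table$label)
}
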