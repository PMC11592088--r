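#' Ensemble specification
#'
#' Three ensemble architectures, each of `n_members` base classifiers of one
#' kind combined by a majority-vote rule: `random_forest` (Gini split
#' criterion), `svm_pca_fdr` and `knn_pca_fdr` (both preceded by
#' standardization, PCA, and Fisher-Discriminant-Ratio ranking of the
#' principal components, keeping the top `fdr_top_m` of the components that
#' explain `pca_variance_kept` of the variance). Member diversity comes from
#' stratified bootstrap resampling with per-member seeds derived from the
#' ensemble seed.
#'
#' @param kind `"random_forest"`, `"svm_pca_fdr"` or `"knn_pca_fdr"`.
#' @param n_members ensemble size (default 16).
#' @param pca_variance_kept variance fraction retained by PCA (default 0.95).
#' @param fdr_top_m number of FDR-ranked components kept (default 10).
#' @param rf_num_trees trees per random-forest member (default 100).
#' @param knn_k neighbours per kNN member (default 5).
#' @param positive_class label treated as positive (default `"malignant"`).
#' @param tie_positive on an exact vote tie, predict the positive class
#'   (default TRUE; the conservative clinical choice for malignancy).
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(kind = c("random_forest", "svm_pca_fdr",
                                   "knn_pca_fdr"),
                          n_members = 16L, pca_variance_kept = 0.95,
                          fdr_top_m = 10L, rf_num_trees = 100L, knn_k = 5L,
                          positive_class = "malignant", tie_positive = TRUE) {
  kind <- match.arg(kind)
  stopifnot(n_members >= 1, pca_variance_kept > 0, pca_variance_kept <= 1,
            fdr_top_m >= 1, rf_num_trees >= 1, knn_k >= 1)
  structure(list(kind = kind, n_members = as.integer(n_members),
                 pca_variance_kept = pca_variance_kept,
                 fdr_top_m = as.integer(fdr_top_m),
                 rf_num_trees = as.integer(rf_num_trees),
                 knn_k = as.integer(knn_k),
                 positive_class = positive_class,
                 tie_positive = isTRUE(tie_positive)),
            class = "ensemble_spec")
}

#' Fisher Discriminant Ratio of each column
#'
#' `(mu1 - mu2)^2 / (s1^2 + s2^2)` per column, the univariate
#' class-separability score used to rank principal components. A column with
#' zero within-class variance in both classes scores `Inf` when the means
#' differ and 0 otherwise.
#'
#' @param X numeric matrix.
#' @param y two-class label vector.
#' @return Numeric vector of FDR scores.
#' @export
fisher_discriminant_ratio <- function(X, y) {
  cls <- unique(y)
  stopifnot(length(cls) == 2)
  a <- X[y == cls[1], , drop = FALSE]
  b <- X[y == cls[2], , drop = FALSE]
  num <- (colMeans(a) - colMeans(b))^2
  den <- apply(a, 2, stats::var) + apply(b, 2, stats::var)
  ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
}

# internal: fit the standardization (+ optional PCA + FDR ranking) chain on
# the training data only
fit_preprocess <- function(X, y, spec) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- scale(X, center = mu, scale = sd_)
  chain <- list(center = mu, scale = sd_, pca = NULL, comp_keep = NULL)
  if (spec$kind != "random_forest") {
    pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    ncomp <- max(1L, which(cum >= spec$pca_variance_kept)[1])
    scores <- pca$x[, seq_len(ncomp), drop = FALSE]
    fdr <- fisher_discriminant_ratio(scores, y)
    keep <- order(fdr, decreasing = TRUE)[seq_len(min(spec$fdr_top_m, ncomp))]
    chain$pca <- pca$rotation[, seq_len(ncomp), drop = FALSE]
    chain$comp_keep <- keep
  }
  chain
}

# internal: apply a fitted preprocessing chain
apply_preprocess <- function(chain, X) {
  Z <- scale(X, center = chain$center, scale = chain$scale)
  if (!is.null(chain$pca)) {
    Z <- (Z %*% chain$pca)[, chain$comp_keep, drop = FALSE]
  }
  Z
}

#' Fit a majority-vote ensemble
#'
#' Fits the preprocessing chain on the full training data, then fits each of
#' the `n_members` base classifiers on a stratified bootstrap resample (with
#' per-member seeds derived from `seed`).
#'
#' @param X numeric training matrix (typically ADASYN-balanced).
#' @param y two-class training labels.
#' @param spec an [ensemble_spec].
#' @param seed integer ensemble seed.
#' @return A `trained_ensemble`.
#' @export
fit_ensemble <- function(X, y, spec = ensemble_spec(), seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), ncol(X) >= 2)
  if (length(unique(y)) < 2) stop("single-class training data")
  y <- factor(y)
  chain <- fit_preprocess(X, as.character(y), spec)
  Z <- apply_preprocess(chain, X)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  members <- lapply(seq_len(spec$n_members), function(m) {
    mseed <- derive_seed(seed, paste0("member_", m))
    set.seed(mseed)
    idx <- unlist(lapply(levels(y), function(cl) {
      w <- which(y == cl)
      sample(w, length(w), replace = TRUE)
    }))
    Zi <- Z[idx, , drop = FALSE]
    yi <- droplevels(y[idx])
    switch(spec$kind,
      random_forest = ranger::ranger(
        x = Zi, y = yi, num.trees = spec$rf_num_trees,
        splitrule = "gini", probability = TRUE, seed = mseed,
        num.threads = 1L),
      svm_pca_fdr = e1071::svm(x = Zi, y = yi, probability = TRUE,
                               scale = FALSE),
      knn_pca_fdr = list(train = Zi, cl = yi,
                         k = min(spec$knn_k, nrow(Zi))))
  })
  structure(list(spec = spec, chain = chain, members = members,
                 classes = levels(y), feature_names = colnames(X),
                 seed = as.integer(seed)),
            class = "trained_ensemble")
}

# internal: positive-class probability of one member on preprocessed data
member_prob <- function(member, Z, spec, classes) {
  pos <- spec$positive_class
  if (spec$kind == "random_forest") {
    p <- stats::predict(member, data = Z, num.threads = 1L)$predictions
    if (pos %in% colnames(p)) p[, pos] else 1 - p[, 1]
  } else if (spec$kind == "svm_pca_fdr") {
    pr <- attr(stats::predict(member, Z, probability = TRUE), "probabilities")
    if (pos %in% colnames(pr)) pr[, pos] else 1 - pr[, 1]
  } else {
    kn <- class::knn(member$train, Z, member$cl, k = member$k, prob = TRUE)
    pwin <- attr(kn, "prob")
    ifelse(as.character(kn) == pos, pwin, 1 - pwin)
  }
}

#' Predict with a trained majority-vote ensemble
#'
#' Each member casts a hard vote (positive-class probability > 0.5; exactly
#' 0.5 counts as positive). The ensemble label is the strict majority of the
#' member votes; an exact tie goes to the positive class when
#' `tie_positive`. The continuous score is the mean member positive-class
#' probability.
#'
#' @param object a `trained_ensemble`.
#' @param X numeric matrix with the training feature schema.
#' @param ... unused.
#' @return A data.frame: `case_id` (rownames of `X` if present), `label`
#'   (hard majority label), `vote_fraction`, `score`.
#' @export
predict.trained_ensemble <- function(object, X, ...) {
  stopifnot(is.matrix(X))
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss) > 0)
    stop("schema mismatch; missing columns: ", paste(miss, collapse = ", "))
  X <- X[, object$feature_names, drop = FALSE]
  Z <- apply_preprocess(object$chain, X)
  spec <- object$spec
  probs <- vapply(object$members, member_prob, numeric(nrow(Z)),
                  Z = Z, spec = spec, classes = object$classes)
  probs <- matrix(probs, nrow = nrow(Z))
  votes <- probs >= 0.5
  vf <- rowMeans(votes)
  pos <- spec$positive_class
  neg <- setdiff(object$classes, pos)
  if (length(neg) == 0) neg <- paste0("not_", pos)
  lab <- ifelse(vf > 0.5 | (vf == 0.5 & spec$tie_positive), pos, neg[1])
  data.frame(case_id = if (!is.null(rownames(X))) rownames(X)
             else as.character(seq_len(nrow(X))),
             label = lab, vote_fraction = vf, score = rowMeans(probs),
             stringsAsFactors = FALSE)
}

#' Per-member hard predictions and scores
#'
#' Used for the "internal testing (mean)" reporting stage, where metrics are
#' averaged over individual ensemble members.
#'
#' @param ensemble a `trained_ensemble`.
#' @param X numeric matrix with the training schema.
#' @return list with `prob` (cases x members positive-class probabilities)
#'   and `label` (cases x members hard labels).
#' @export
member_predictions <- function(ensemble, X) {
  X <- X[, ensemble$feature_names, drop = FALSE]
  Z <- apply_preprocess(ensemble$chain, X)
  spec <- ensemble$spec
  probs <- vapply(ensemble$members, member_prob, numeric(nrow(Z)),
                  Z = Z, spec = spec, classes = ensemble$classes)
  probs <- matrix(probs, nrow = nrow(Z))
  pos <- spec$positive_class
  neg <- setdiff(ensemble$classes, pos)[1]
  lab <- matrix(ifelse(probs >= 0.5, pos, neg), nrow = nrow(Z))
  list(prob = probs, label = lab)
}
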