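test_that("ADASYN targets the study's G = 62 and roughly balances classes", {
  d <- two_blob_data(102, 40, sep = 2)
  out <- adasyn_oversample(d$X, d$y, adasyn_config(beta = 1, seed = 3))
  n_new <- sum(out$synthetic)
  # G = (102 - 40) * 1 = 62, met up to per-point rounding slack
  expect_lte(abs(n_new - 62), 40)
  expect_gte(n_new, 62 - 20)
  expect_equal(sum(out$y == "benign"), 102)
  # originals pass through unchanged, in order
  expect_identical(out$X[seq_len(142), ], d$X)
})

test_that("ADASYN synthetics lie on minority-minority segments", {
  d <- two_blob_data(30, 12, sep = 3)
  out <- adasyn_oversample(d$X, d$y, adasyn_config(seed = 5))
  Xmin <- d$X[d$y == "malignant", ]
  synth <- out$X[out$synthetic, , drop = FALSE]
  expect_gt(nrow(synth), 0)
  on_segment <- function(s) {
    for (i in seq_len(nrow(Xmin))) for (j in seq_len(nrow(Xmin))) {
      a <- Xmin[i, ]; b <- Xmin[j, ]
      ab <- b - a; as_ <- s - a
      cross <- ab[1] * as_[2] - ab[2] * as_[1]
      dot <- sum(as_ * ab)
      if (abs(cross) < 1e-8 && dot >= -1e-8 && dot <= sum(ab^2) + 1e-8)
        return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))
  # convex hull bound (coordinate-wise box is implied)
  expect_true(all(synth[, 1] >= min(Xmin[, 1]) - 1e-8 &
                  synth[, 1] <= max(Xmin[, 1]) + 1e-8))
})

test_that("ADASYN spreads synthetics uniformly when no majority neighbours exist", {
  d <- two_blob_data(60, 20, sep = 50, seed = 7)  # fully separable
  out <- adasyn_oversample(d$X, d$y, adasyn_config(seed = 7))
  # all r_i = 0 -> uniform weights -> per-point counts differ by <= 1
  expect_lte(diff(range(out$g)), 1)
  expect_equal(sum(out$g), sum(out$synthetic))
})

test_that("ADASYN is deterministic and reduces k when the minority is tiny", {
  d <- two_blob_data(20, 4, sep = 2, seed = 9)
  expect_warning(a <- adasyn_oversample(d$X, d$y,
                                        adasyn_config(k_neighbors = 5,
                                                      seed = 1)),
                 "reducing k")
  suppressWarnings(b <- adasyn_oversample(d$X, d$y,
                                          adasyn_config(k_neighbors = 5,
                                                        seed = 1)))
  expect_identical(a$X, b$X)
})

test_that("every ensemble kind separates a separable toy problem in training", {
  d <- two_blob_data(40, 40, sep = 6, seed = 11)
  for (kind in c("random_forest", "svm_pca_fdr", "knn_pca_fdr")) {
    ens <- fit_ensemble(d$X, d$y, ensemble_spec(kind), seed = 2)
    pr <- predict(ens, d$X)
    expect_equal(mean(pr$label == d$y), 1, label = kind)
    mp <- member_predictions(ens, d$X)
    expect_equal(mean(mp$label == matrix(d$y, nrow(d$X),
                                         ncol(mp$label))), 1,
                 label = paste(kind, "members"))
  }
})

test_that("Fisher discriminant ratio ranks the separating component first", {
  set.seed(13)
  X <- cbind(sep = c(stats::rnorm(30, 0, 1), stats::rnorm(30, 6, 1)),
             flat1 = stats::rnorm(60), flat2 = stats::rnorm(60))
  y <- rep(c("a", "b"), each = 30)
  fdr <- fisher_discriminant_ratio(X, y)
  expect_equal(unname(which.max(fdr)), 1)
  # direct formula check on the first column
  m1 <- mean(X[1:30, 1]); m2 <- mean(X[31:60, 1])
  v1 <- stats::var(X[1:30, 1]); v2 <- stats::var(X[31:60, 1])
  expect_equal(unname(fdr[1]), (m1 - m2)^2 / (v1 + v2))
})

test_that("keeping all PCA components makes the FDR cut a pure reordering", {
  d <- two_blob_data(30, 30, sep = 3, seed = 15)
  spec <- ensemble_spec("svm_pca_fdr", fdr_top_m = 100L,
                        pca_variance_kept = 1)
  ens <- fit_ensemble(d$X, d$y, spec, seed = 1)
  expect_setequal(ens$chain$comp_keep, seq_len(ncol(ens$chain$pca)))
})

test_that("majority vote follows the strict-majority and tie rules", {
  # hand-built two-member kNN ensemble whose members disagree at the origin
  spec <- ensemble_spec("knn_pca_fdr", n_members = 2L, knn_k = 1L)
  chain <- list(center = c(f1 = 0, f2 = 0), scale = c(f1 = 1, f2 = 1),
                pca = NULL, comp_keep = NULL)
  mem <- function(lab) list(train = matrix(0, 1, 2), cl = factor(lab), k = 1)
  ens <- structure(list(spec = spec, chain = chain,
                        members = list(mem("benign"), mem("malignant")),
                        classes = c("benign", "malignant"),
                        feature_names = c("f1", "f2"), seed = 1L),
                   class = "trained_ensemble")
  pr <- predict(ens, matrix(0, 1, 2, dimnames = list(NULL, c("f1", "f2"))))
  expect_equal(pr$vote_fraction, 0.5)
  expect_equal(pr$label, "malignant")  # tie goes to the positive class

  spec2 <- spec; spec2$tie_positive <- FALSE
  ens$spec <- spec2
  expect_equal(predict(ens, matrix(0, 1, 2,
                                   dimnames = list(NULL,
                                                   c("f1", "f2"))))$label,
               "benign")
})

test_that("vote fractions are invariant to member order", {
  d <- two_blob_data(25, 25, sep = 1.5, seed = 17)
  ens <- fit_ensemble(d$X, d$y, ensemble_spec("random_forest"), seed = 3)
  shuffled <- ens
  shuffled$members <- rev(ens$members)
  a <- predict(ens, d$X)
  b <- predict(shuffled, d$X)
  expect_equal(a$vote_fraction, b$vote_fraction)
  expect_equal(a$score, b$score)
})

test_that("prediction rejects schema mismatches by name", {
  d <- two_blob_data(20, 20, sep = 3, seed = 19)
  ens <- fit_ensemble(d$X, d$y, ensemble_spec("random_forest"), seed = 1)
  bad <- d$X
  colnames(bad) <- c("f1", "other")
  expect_error(predict(ens, bad), "f2")
})
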