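test_that("CV plans stratify within one case and cover each fold once", {
  y8 <- rep(c("benign", "malignant"), each = 4)
  p8 <- make_cv_plan(y8, seed = 1)
  expect_equal(sort(unique(p8$fold)), 1:4)
  expect_true(all(table(p8$fold) == 2))
  tested <- sort(unlist(lapply(p8$rotations, `[[`, "test")))
  expect_equal(tested, 1:8)  # disjoint, union = all cases

  y142 <- c(rep("benign", 102), rep("malignant", 40))
  p <- make_cv_plan(y142, seed = 5)
  tab <- table(p$fold, y142)
  expect_true(all(abs(tab[, "benign"] - 25.5) <= 1))
  expect_true(all(tab[, "malignant"] == 10))
  for (rot in p$rotations) {
    expect_length(intersect(rot$train, rot$test), 0)
    expect_length(intersect(rot$train, rot$validation), 0)
    expect_setequal(c(rot$train, rot$validation, rot$test), seq_along(y142))
  }
  p2 <- make_cv_plan(y142, seed = 6)
  expect_false(identical(p$fold, p2$fold))
})

test_that("compute_metrics reproduces the external-test worked example", {
  # 21 cases: 6 malignant all called malignant; 13 of 15 benign called benign
  y_true <- c(rep("malignant", 6), rep("benign", 15))
  y_pred <- c(rep("malignant", 6), rep("malignant", 2), rep("benign", 13))
  m <- compute_metrics(y_true, y_pred, positive = "malignant")
  expect_equal(unname(m["accuracy"]), 100 * 19 / 21, tolerance = 1e-10)
  expect_equal(unname(m["sensitivity"]), 100)
  expect_equal(unname(m["specificity"]), 100 * 13 / 15, tolerance = 1e-10)
  expect_equal(unname(m["ppv"]), 75)
  expect_equal(unname(m["npv"]), 100)

  perfect <- compute_metrics(y_true, y_true, as.numeric(y_true == "malignant"))
  expect_true(all(perfect == 100))

  const <- compute_metrics(y_true, y_pred, rep(0.5, 21))
  expect_equal(unname(const["roc_auc"]), 50)
})

test_that("rank-based AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- sample(c("benign", "malignant"), 60, TRUE)
  s <- stats::rnorm(60) + (y == "malignant")
  s[1:10] <- round(s[1:10], 1)  # induce some ties
  mine <- roc_auc(y, s, "malignant")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = s, levels = c("benign", "malignant"),
    direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("signed-rank test matches exact enumeration", {
  # 6 uniformly positive differences: one-sided p = 1 / 2^6
  expect_equal(wilcoxon_vs_chance(c(55, 60, 52, 58, 70, 65), 50), 1 / 64)
  # all samples at the null: p = 1
  expect_equal(wilcoxon_vs_chance(rep(50, 8), 50), 1)
  # symmetric about the null: p near one half
  p <- wilcoxon_vs_chance(c(48, 52, 46, 54, 44, 56, 42, 58), 50)
  expect_gt(p, 0.3); expect_lt(p, 0.7)
})

test_that("model selection follows internal-test mean AUC with tie-breaks", {
  fake <- function(mean_auc, maj_auc) {
    structure(list(summary = data.frame(
      stage = c("internal_mean", "internal_majority"),
      metric = "roc_auc", value = c(mean_auc, maj_auc))),
      class = "cv_result")
  }
  res <- list(rf = fake(84, 85), svm = fake(79, 80), knn = fake(77, 79))
  expect_identical(select_best_model(res), "rf")
  tie <- list(a = fake(80, 70), b = fake(80, 75))
  expect_identical(select_best_model(tie), "b")
  expect_identical(select_best_model(list(only = fake(60, 60))), "only")
})

test_that("Mann-Whitney feature stats match enumeration and Holm ordering", {
  tab <- data.frame(case_id = sprintf("c%d", 1:6),
                    label = rep(c("benign", "malignant"), each = 3),
                    sep = c(1, 2, 3, 10, 11, 12),
                    check.names = FALSE)
  st <- univariate_feature_stats(tab)
  expect_equal(st$statistic_u, 9)       # complete separation, 3 vs 3
  expect_equal(st$p_raw, 0.1)           # 2 / C(6,3)
  expect_equal(st$p_holm, 0.1)

  # Holm on three features with known raw p ordering
  set.seed(23)
  n <- 40
  y <- rep(c("benign", "malignant"), each = n / 2)
  tab3 <- data.frame(case_id = sprintf("c%d", 1:n), label = y,
                     strong = ifelse(y == "malignant", 3, 0) + stats::rnorm(n),
                     medium = ifelse(y == "malignant", 1, 0) + stats::rnorm(n),
                     none = stats::rnorm(n), check.names = FALSE)
  st3 <- univariate_feature_stats(tab3)
  expect_true(all(st3$p_holm >= st3$p_raw))
  expect_identical(st3$feature[1], "strong")
  expect_true(all(diff(st3$p_holm) >= 0))
  expect_identical(st3$stars[st3$p_holm < 0.005][1], "**")

  # constant feature: p = 1
  tabc <- data.frame(case_id = sprintf("c%d", 1:8),
                     label = rep(c("benign", "malignant"), each = 4),
                     flat = rep(2, 8), check.names = FALSE)
  expect_equal(univariate_feature_stats(tabc)$p_raw, 1)
})

test_that("median CIs bracket the median and use order statistics", {
  set.seed(25)
  x <- stats::rnorm(41)
  ci <- median_ci(x)
  expect_lte(ci[2], ci[1])
  expect_gte(ci[3], ci[1])
  expect_true(ci[2] %in% x && ci[3] %in% x)
})

test_that("nested CV keeps test folds out of all fitted preprocessing", {
  set.seed(27)
  n <- 48
  y <- rep(c("benign", "malignant"), each = n / 2)
  X <- cbind(matrix(stats::rnorm(n * 3), n, 3),
             sig = ifelse(y == "malignant", 2, 0) + stats::rnorm(n))
  colnames(X) <- paste0("f", 1:4)
  plan <- make_cv_plan(y, seed = 2)
  spec <- ensemble_spec("svm_pca_fdr", n_members = 4L)
  res1 <- run_nested_cv(X, y, spec, plan, adasyn_config(seed = 1), seed = 9)
  # perturb the rotation-1 validation and test folds only
  X2 <- X
  rot <- plan$rotations[[1]]
  X2[c(rot$validation, rot$test), ] <-
    X2[c(rot$validation, rot$test), ] + 100
  res2 <- run_nested_cv(X2, y, spec, plan, adasyn_config(seed = 1), seed = 9)
  expect_identical(res1$ensembles[[1]]$chain, res2$ensembles[[1]]$chain)
  tr1 <- res1$member_metrics[res1$member_metrics$rotation == 1 &
                               res1$member_metrics$stage == "training", ]
  tr2 <- res2$member_metrics[res2$member_metrics$rotation == 1 &
                               res2$member_metrics$stage == "training", ]
  expect_equal(tr1, tr2)
})

test_that("each case is internal-tested exactly once and summaries are complete", {
  set.seed(29)
  n <- 32
  y <- rep(c("benign", "malignant"), each = n / 2)
  X <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(sprintf("c%02d", 1:n), paste0("f", 1:4)))
  X[, 1] <- X[, 1] + 2 * (y == "malignant")
  plan <- make_cv_plan(y, seed = 3)
  res <- run_nested_cv(X, y, ensemble_spec("random_forest", n_members = 4L),
                       plan, adasyn_config(seed = 2), seed = 4)
  expect_setequal(res$pooled_test$case_id, rownames(X))
  expect_equal(nrow(res$pooled_test), n)
  expect_setequal(unique(res$summary$stage),
                  c("training", "validation", "internal_mean",
                    "internal_majority"))
  expect_true(all(res$summary$value >= res$summary$ci_lo - 1e-9, na.rm = TRUE))
  expect_true(all(res$summary$value <= res$summary$ci_hi + 1e-9, na.rm = TRUE))
  # member-level samples: 4 members x 4 rotations x 3 stages
  expect_equal(nrow(res$member_metrics), 4 * 4 * 3)
})

test_that("permuted labels drive internal mean AUC toward chance", {
  set.seed(31)
  n <- 40
  X <- matrix(stats::rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  aucs <- vapply(1:3, function(i) {
    y <- sample(rep(c("benign", "malignant"), each = n / 2))
    plan <- make_cv_plan(y, seed = i)
    res <- run_nested_cv(X, y, ensemble_spec("random_forest",
                                             n_members = 4L),
                         plan, adasyn_config(seed = i), seed = i)
    s <- res$summary
    s$value[s$stage == "internal_mean" & s$metric == "roc_auc"]
  }, numeric(1))
  expect_gt(mean(aucs), 30)
  expect_lt(mean(aucs), 70)
})

test_that("external testing pools members deterministically with both orientations", {
  d_tr <- two_blob_data(30, 14, sep = 4, seed = 33)
  plan <- make_cv_plan(d_tr$y, seed = 1)
  res <- run_nested_cv(d_tr$X, d_tr$y,
                       ensemble_spec("random_forest", n_members = 4L),
                       plan, adasyn_config(seed = 1), seed = 1)
  d_ex <- two_blob_data(15, 6, sep = 4, seed = 34)
  et <- external_test(res, d_ex$X, d_ex$y)
  expect_setequal(unique(et$metrics$stage),
                  c("external", "external_benign_positive"))
  expect_equal(nrow(et$predictions), 21)
  # duplicating the external set duplicates the per-case predictions exactly
  et2 <- external_test(res, rbind(d_ex$X, d_ex$X), c(d_ex$y, d_ex$y))
  expect_equal(et2$predictions$label, rep(et$predictions$label, 2))
  # orientation swap exchanges sensitivity and specificity
  pos <- et$metrics[et$metrics$stage == "external", ]
  neg <- et$metrics[et$metrics$stage == "external_benign_positive", ]
  expect_equal(pos$value[pos$metric == "sensitivity"],
               neg$value[neg$metric == "specificity"])
})

test_that("report export writes the full file set", {
  d <- two_blob_data(16, 16, sep = 4, seed = 35)
  plan <- make_cv_plan(d$y, seed = 1)
  res <- run_nested_cv(d$X, d$y, ensemble_spec("random_forest",
                                               n_members = 2L),
                       plan, adasyn_config(seed = 1), seed = 1)
  dir <- withr::local_tempdir()
  tab <- data.frame(case_id = sprintf("c%d", seq_along(d$y)), label = d$y,
                    d$X, check.names = FALSE)
  uni <- univariate_feature_stats(tab)
  export_reports(dir, list(rf = res), univariate = uni, table = tab)
  expect_true(all(file.exists(file.path(
    dir, c("metrics.csv", "metrics.json", "roc_rf.csv",
           "univariate_stats.csv", "feature_values_long.csv")))))
  roc <- utils::read.csv(file.path(dir, "roc_rf.csv"))
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1, na.rm = TRUE))
})
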