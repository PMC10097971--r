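separable_table <- function(n = 100, seed = 41) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    tibble::tibble(
      p_delta = y * 4 + rnorm(n, sd = 0.3),
      p_theta = -y * 3 + rnorm(n, sd = 0.3),
      label = y
    )
  })
}

test_that("the SVM kernel-scale presets evaluate to the published constants", {
  ks <- svm_kernel_scales(8)
  expect_equal(signif(unname(ks), 2), c(0.71, 2.8, 11))
  expect_equal(unname(ks["medium"]), sqrt(8))
})

test_that("logistic prediction is the sigmoid of the affine score", {
  expect_equal(logistic_predict(c(0, 0), 5), 0.5)
  expect_equal(logistic_predict(c(0, 1), 0), 0.5)
  expect_gt(logistic_predict(c(0, 1), 50), 0.999)
  expect_equal(logistic_predict(c(log(3), 0), 7), 0.75)
  m <- logistic_predict(c(1, 2, -1), matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(m, stats::plogis(c(3, 0)))
  expect_error(logistic_predict(c(1, 2), matrix(1, 1, 2)), "coefficients")
})

test_that("the preset catalogue is closed and every preset trains and predicts", {
  cat <- classifier_presets()
  expect_equal(nrow(cat), 22)
  expect_setequal(
    unique(cat$family),
    c("tree", "discriminant", "logistic", "naive_bayes", "svm", "knn", "ensemble")
  )
  expect_error(classifier_preset("super_tree"), "unknown preset")

  tab <- separable_table(300)
  X <- as.matrix(tab[c("p_delta", "p_theta")])
  y <- tab$label
  withr::with_seed(42, {
    for (nm in cat$preset) {
      fit <- fit_model <- drowsEEG:::fit_model(X, y, classifier_preset(nm))
      pr <- drowsEEG:::predict_model(fit, X)
      expect_length(pr$class, nrow(X))
      expect_true(all(pr$class %in% c(0L, 1L)), info = nm)
      expect_true(all(is.finite(pr$score)), info = nm)
      # separable data: every preset should beat chance comfortably in-sample
      expect_gt(mean(pr$class == y), 0.8)
    }
  })
})

test_that("cross-validation is stratified, deterministic and leak-free", {
  tab <- separable_table(100)
  cv <- cross_validate(tab, "lda", seed = 7, features = c("p_delta", "p_theta"))
  expect_gte(mean(cv$predictions$pred == cv$predictions$truth), 0.95)
  # every row predicted exactly once
  expect_equal(sort(cv$predictions$row), seq_len(100))
  # stratification keeps both classes in each fold
  per_fold <- tapply(cv$predictions$truth, cv$predictions$fold, function(v) length(unique(v)))
  expect_true(all(per_fold == 2))

  cv2 <- cross_validate(tab, "lda", seed = 7, features = c("p_delta", "p_theta"))
  expect_identical(cv$predictions, cv2$predictions)

  cvb <- cross_validate(tab, "bagged_trees", seed = 9, features = c("p_delta", "p_theta"))
  cvb2 <- cross_validate(tab, "bagged_trees", seed = 9, features = c("p_delta", "p_theta"))
  expect_identical(cvb$predictions, cvb2$predictions)

  small <- tab[c(1:4, 51:98), ]
  expect_warning(
    cross_validate(small, "lda", n_folds = 10, features = c("p_delta", "p_theta")),
    "fold count reduced"
  )
})

test_that("permuted labels give chance-level pooled accuracy", {
  withr::with_seed(43, {
    tab <- separable_table(300)
    tab$label <- sample(tab$label)
  })
  for (nm in c("medium_tree", "lda", "logistic", "weighted_knn", "bagged_trees")) {
    cv <- cross_validate(tab, nm, seed = 11, features = c("p_delta", "p_theta"))
    acc <- mean(cv$predictions$pred == cv$predictions$truth)
    expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 300) + 1e-9)
  }
})

test_that("glance and tidy summarize cross-validation results coherently", {
  cv <- cross_validate(separable_table(80), "lda", seed = 3,
    features = c("p_delta", "p_theta")
  )
  g <- glance(cv)
  expect_equal(g$n, 80)
  expect_true(g$auc >= g$accuracy - 0.1)
  td <- tidy(cv)
  expect_equal(sum(td$n), 80)
  expect_equal(sum(td$tp + td$tn + td$fp + td$fn), 80)
})

test_that("the exhaustive search enumerates 211 combinations for 8 features", {
  tab <- make_feature_table(n = 60, seed = 44)
  res <- exhaustive_feature_search(tab, "logistic", n_folds = 2, seed = 5)
  expect_equal(nrow(res), 211)
  expect_equal(
    sort(unique(res$n_features)),
    c(2:5, 8)
  )
  expect_true(all(diff(res$accuracy) <= 0))
})

test_that("search accuracy saturates on a label-leaking feature and ignores duplicates", {
  withr::with_seed(45, {
    n <- 60
    y <- rep(c(0L, 1L), each = n / 2)
    tab <- tibble::tibble(
      a = as.numeric(y), b = rnorm(n), c = rnorm(n), label = y
    )
  })
  res <- exhaustive_feature_search(tab, "medium_tree",
    orders = 2, include_full = FALSE,
    n_folds = 5, seed = 6, features = c("a", "b", "c")
  )
  with_a <- grepl("(^|\\+)a($|\\+)", res$features)
  expect_true(all(res$accuracy[with_a] >= 0.95))

  dup <- tab
  dup$b2 <- dup$b
  res2 <- exhaustive_feature_search(dup, "lda",
    orders = 2, include_full = FALSE,
    n_folds = 5, seed = 6, features = c("a", "b", "b2")
  )
  expect_equal(
    res2$accuracy[res2$features == "a+b"],
    res2$accuracy[res2$features == "a+b2"]
  )
})

test_that("ensemble tuning returns the default under a unit budget and never regresses", {
  tab <- separable_table(80)
  t1 <- tune_best(tab, budget = 1, seed = 2, features = c("p_delta", "p_theta"))
  expect_equal(t1$preset$name, "bagged_trees")
  expect_equal(nrow(t1$trace), 1)

  t5 <- tune_best(tab, budget = 5, seed = 2, features = c("p_delta", "p_theta"))
  expect_gte(t5$accuracy, t5$trace$accuracy[1])
  expect_equal(t5$accuracy, max(t5$trace$accuracy))

  t5b <- tune_best(tab, budget = 5, seed = 2, features = c("p_delta", "p_theta"))
  expect_identical(tidy(t5), tidy(t5b))
  expect_equal(glance(t5)$candidates, 5)
})
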