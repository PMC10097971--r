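test_that("confusion counts are exact for the canonical cases", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cm[c("tp", "fn", "tn", "fp")]), c(tp = 1, fn = 1, tn = 1, fp = 1))

  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0)

  inverted <- confusion(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(inverted$tp + inverted$tn, 0)

  expect_error(confusion(c(1, 0), c(1, 2)), "0/1")
  expect_error(confusion(c(1, 0), 1), "length")
})

test_that("metrics have their defining identities on random confusion matrices", {
  withr::with_seed(51, {
    for (i in 1:25) {
      counts <- rmultinom(1, 200, c(0.3, 0.2, 0.2, 0.3))[, 1] + 1
      cm <- structure(
        list(tp = counts[1], fn = counts[2], fp = counts[3], tn = counts[4]),
        class = "confusion_matrix"
      )
      m <- compute_metrics(cm)
      n <- sum(unlist(cm[1:4]))
      expect_equal(m$accuracy, (cm$tp + cm$tn) / n)
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
      expect_equal(m$fpr, 1 - m$specificity)
      expect_true(m$mcc >= -1 && m$mcc <= 1)
      expect_lte(m$kappa, 1)
    }
  })
})

test_that("degenerate confusion matrices flag undefined ratios instead of Inf", {
  m <- compute_metrics(structure(list(tp = 0, fn = 0, fp = 0, tn = 10),
    class = "confusion_matrix"
  ))
  expect_true(is.na(m$recall) && m$flag_recall)
  expect_true(is.na(m$mcc) && m$flag_mcc)
  expect_equal(m$accuracy, 1)

  perfect <- compute_metrics(confusion(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$mcc, 1)

  coin <- compute_metrics(structure(list(tp = 25, fn = 25, fp = 25, tn = 25),
    class = "confusion_matrix"
  ))
  expect_equal(coin$accuracy, 0.5)
  expect_equal(coin$mcc, 0)
  expect_equal(coin$kappa, 0)
})

test_that("rates reconstruct a normalized confusion matrix correctly", {
  cm <- confusion_from_rates(0.897, 0.800, 0.571)
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, 1)
  expect_equal(cm$tp / (cm$tp + cm$fn), 0.897)
  expect_equal(cm$tn / (cm$tn + cm$fp), 0.800)
  expect_equal(cm$tp + cm$fn, 0.571)
})

test_that("ROC/AUC matches closed forms, brute force and an independent library", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)

  withr::with_seed(52, {
    sc <- rnorm(4000)
    y <- rbinom(4000, 1, 0.5)
    expect_equal(roc_auc(sc, y)$auc, 0.5, tolerance = 0.03)
  })

  withr::with_seed(53, {
    for (i in 1:10) {
      n <- sample(20:100, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      sc <- round(rnorm(n), 1) # coarse scores force ties
      r <- roc_auc(sc, y)
      expect_equal(r$auc, brute_auc(sc, y), tolerance = 1e-12)
      if (requireNamespace("pROC", quietly = TRUE)) {
        ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE, direction = "<")))
        expect_equal(r$auc, ref, tolerance = 1e-9)
      }
    }
  })
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("two-way replicated ANOVA matches a hand sum-of-squares oracle", {
  withr::with_seed(54, {
    d <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v", "w"), rep = 1:4)
    d$val <- rnorm(nrow(d)) + 2 * (d$a == "y") + 0.5 * (d$b == "w")
    res <- anova2_replicated(d, "val", "a", "b")
    ref <- brute_anova2(d$val, d$a, d$b)
    expect_equal(res$statistic, ref$statistic, tolerance = 1e-10)
    expect_equal(res$p_value, ref$p_value, tolerance = 1e-10)
  })
})

test_that("ANOVA flags constant data and detects a planted factor effect", {
  d <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3)
  d$val <- 5
  res <- anova2_replicated(d, "val", "a", "b")
  expect_true(all(res$flag_undefined))

  hits <- vapply(1:20, function(i) {
    withr::with_seed(500 + i, {
      d$val <- rnorm(nrow(d)) + 4 * (d$a == "y")
      anova2_replicated(d, "val", "a", "b")$p_value[1] < 0.05
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  unb <- d[-1, ]
  expect_error(anova2_replicated(unb, "val", "a", "b"), "balanced")
})

test_that("channel selection applies the Bonferroni-corrected paired tests", {
  withr::with_seed(55, {
    subj <- sprintf("S%02d", 1:12)
    reports <- tidyr::expand_grid(channel = c("Fp1", "Fp2", "F7", "F8", "O1", "O2"),
      subject_id = subj
    )
    reports$accuracy <- 0.8 + 0.06 * (reports$channel == "F8") +
      rnorm(nrow(reports), sd = 0.01)
  })
  res <- select_coi(reports)
  expect_equal(res$coi, "F8")
  expect_equal(res$corrected_alpha, 0.01)
  expect_equal(nrow(res$tests), 5)
  expect_true(all(res$tests$significant))
  expect_equal(glance(res)$coi, "F8")

  flat <- reports
  flat$accuracy <- rep(c(0.8, 0.81), length.out = nrow(flat))
  flat$accuracy <- stats::ave(flat$accuracy, flat$subject_id) # identical per subject
  res_flat <- select_coi(flat)
  expect_false(any(res_flat$tests$significant %in% TRUE))

  one_subj <- reports[reports$subject_id == "S01", ]
  expect_warning(r1 <- select_coi(one_subj), "fewer than 2 subjects")
  expect_true(is.character(r1$coi))
})
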